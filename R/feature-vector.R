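#' Construct a feature vector
#'
#' The universal descriptor output type: an ordered, named numeric vector.
#' Names must be unique and every value finite.
#'
#' @param values numeric vector of finite values.
#' @param names character vector of unique names, same length as `values`.
#' @return A named numeric vector of class `feature_vector`.
#' @export
#' @examples
#' feature_vector(c(1, 2), c("a", "b"))
feature_vector <- function(values, names = base::names(values)) {
  if (is.null(names)) stop("feature_vector requires names")
  values <- as.numeric(values)
  names <- as.character(names)
  if (length(values) != length(names))
    stop("values and names differ in length: ", length(values), " vs ", length(names))
  if (anyDuplicated(names))
    stop("duplicate feature names: ",
         paste(utils::head(unique(names[duplicated(names)]), 5L), collapse = ", "))
  if (!all(is.finite(values)))
    stop("non-finite feature values at: ",
         paste(utils::head(names[!is.finite(values)], 5L), collapse = ", "))
  structure(stats::setNames(values, names), class = c("feature_vector", "numeric"))
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("<feature_vector> ", length(x), " features\n", sep = "")
  print(utils::head(unclass(x), 10L), ...)
  if (length(x) > 10L) cat("... (", length(x) - 10L, " more)\n", sep = "")
  invisible(x)
}

# concatenate feature vectors, enforcing global name uniqueness
fv_concat <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) &&
      !inherits(parts[[1L]], "feature_vector")) parts <- parts[[1L]]
  v <- unlist(lapply(parts, unclass), use.names = TRUE)
  feature_vector(v)
}
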