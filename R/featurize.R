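# Batch featurization: configuration, the record-loop driver used by the
# command-line front end, and tabular output. Per-record failures are
# skipped with a logged reason (never silently dropped): rows written plus
# rows skipped always equals records read.

PROTEIN_FAMILIES <- c("aac", "dpc", "tpc", "moreau_broto", "moran", "geary",
                      "ctd", "conjoint_triad", "socn", "qso", "pseaac",
                      "apseaac", "all")
DNA_FAMILIES <- c("kmer", "rckmer", "dac", "dcc", "dacc", "tac", "tcc",
                  "tacc", "psednc", "psetnc", "scpsednc", "scpsetnc", "all")

#' Build a featurization run configuration
#'
#' Flags override values from an optional YAML or JSON configuration file;
#' defaults match every family's documented defaults. Unknown family names
#' are rejected with the list of valid ones.
#'
#' @param path optional YAML/JSON config file.
#' @param ... individual overrides: `input`, `format` (`"fasta"`,
#'   `"strings"`, `"smiles"`, `"sdf"`), `kind` (`"protein"`, `"dna"`,
#'   `"chem"`, `"fingerprint"`), `families`, `params` (named list: `lambda`,
#'   `w`, `maxlag`, `k`), `output`, `out_format` (`"csv"`, `"tsv"`,
#'   `"json"`), `digits`, `standardize` (logical, chem only).
#' @return A `run_config` list.
#' @export
load_config <- function(path = NULL, ...) {
  cfg <- list(input = NULL, format = NULL, kind = "protein",
              families = "all", params = list(), output = NULL,
              out_format = "csv", digits = 6L, standardize = TRUE)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    file_cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::fromJSON(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    cfg[names(file_cfg)] <- file_cfg
  }
  overrides <- list(...)
  overrides <- overrides[!vapply(overrides, is.null, logical(1L))]
  for (nm in setdiff(names(overrides), "params")) cfg[[nm]] <- overrides[[nm]]
  if (!is.null(overrides$params))
    cfg$params[names(overrides$params)] <- overrides$params
  if (!cfg$kind %in% c("protein", "dna", "chem", "fingerprint"))
    stop("kind must be protein, dna, chem or fingerprint")
  valid <- switch(cfg$kind,
    protein = PROTEIN_FAMILIES, dna = DNA_FAMILIES,
    chem = c(names(CHEM_GROUPS), "all"),
    fingerprint = FP_REGISTRY$name)
  bad <- setdiff(cfg$families, valid)
  if (length(bad))
    stop("unknown famil", if (length(bad) > 1) "ies: " else "y: ",
         paste(bad, collapse = ", "), "; valid for kind '", cfg$kind, "': ",
         paste(valid, collapse = ", "))
  if (is.null(cfg$format))
    cfg$format <- if (cfg$kind %in% c("protein", "dna")) "fasta" else "smiles"
  structure(cfg, class = "run_config")
}

# read input records as data.frame(id, payload)
read_records <- function(cfg) {
  if (is.null(cfg$input) || !file.exists(cfg$input))
    stop("input file not found: ", if (is.null(cfg$input)) "<missing>" else cfg$input)
  switch(cfg$format,
    fasta = {
      r <- read_fasta(cfg$input)
      data.frame(id = r$id, payload = r$sequence, stringsAsFactors = FALSE)
    },
    strings = {
      lines <- trimws(readLines(cfg$input, warn = FALSE))
      lines <- lines[nzchar(lines)]
      parts <- strsplit(lines, "\t")
      data.frame(
        id = vapply(seq_along(parts), function(i)
          if (length(parts[[i]]) > 1L) parts[[i]][2L] else paste0("seq", i),
          character(1L)),
        payload = vapply(parts, `[`, character(1L), 1L),
        stringsAsFactors = FALSE)
    },
    smiles = {
      lines <- trimws(readLines(cfg$input, warn = FALSE))
      lines <- lines[nzchar(lines)]
      parts <- strsplit(lines, "[\t ]+")
      data.frame(
        id = vapply(seq_along(parts), function(i)
          if (length(parts[[i]]) > 1L) parts[[i]][2L] else paste0("mol", i),
          character(1L)),
        payload = vapply(parts, `[`, character(1L), 1L),
        stringsAsFactors = FALSE)
    },
    sdf = {
      txt <- paste(readLines(cfg$input, warn = FALSE), collapse = "\n")
      mols <- parse_structures(txt, "sdf")
      data.frame(
        id = vapply(seq_along(mols), function(i)
          if (nzchar(mols[[i]]$title)) mols[[i]]$title else paste0("mol", i),
          character(1L)),
        payload = seq_along(mols),
        stringsAsFactors = FALSE) -> d
      attr(d, "mols") <- mols
      d
    },
    stop("unknown input format: ", cfg$format))
}

featurize_protein <- function(seq, families, p) {
  lambda <- p$lambda %||% 30L
  lambda_a <- p$lambda_apseaac %||% 15L
  w <- p$w %||% 0.05
  maxlag <- p$maxlag %||% 30L
  if ("all" %in% families) return(protein_all(seq))
  parts <- lapply(families, function(f) switch(f,
    aac = prefix_fv(peptide_composition(seq, 1L), "aac."),
    dpc = prefix_fv(peptide_composition(seq, 2L), "dpc."),
    tpc = prefix_fv(peptide_composition(seq, 3L), "tpc."),
    moreau_broto = autocorrelation(seq, "moreau_broto", maxlag = maxlag),
    moran = autocorrelation(seq, "moran", maxlag = maxlag),
    geary = autocorrelation(seq, "geary", maxlag = maxlag),
    ctd = ctd(seq),
    conjoint_triad = conjoint_triad(seq),
    socn = socn(seq, maxlag = maxlag),
    qso = qso(seq, maxlag = maxlag, w = p$w_qso %||% 0.1),
    pseaac = pseaac(seq, lambda = lambda, w = w),
    apseaac = apseaac(seq, lambda = lambda_a, w = w)))
  fv_concat(parts)
}

featurize_dna <- function(seq, families, p) {
  lambda <- p$lambda %||% 2L
  w <- p$w %||% 0.05
  maxlag <- p$maxlag %||% 2L
  k <- p$k %||% 2L
  if ("all" %in% families) return(dna_all(seq))
  p2 <- oligo_properties(2L); p3 <- oligo_properties(3L)
  parts <- lapply(families, function(f) switch(f,
    kmer = kmer_composition(seq, k),
    rckmer = kmer_composition(seq, k, canonical = TRUE),
    dac = covariance(seq, 2L, "auto", p2, maxlag),
    dcc = covariance(seq, 2L, "cross", p2, maxlag),
    dacc = covariance(seq, 2L, "autocross", p2, maxlag),
    tac = covariance(seq, 3L, "auto", p3, maxlag),
    tcc = covariance(seq, 3L, "cross", p3, maxlag),
    tacc = covariance(seq, 3L, "autocross", p3, maxlag),
    psednc = pse_composition(seq, 2L, lambda, w, p2),
    psetnc = pse_composition(seq, 3L, lambda, w, p3),
    scpsednc = pse_composition(seq, 2L, lambda, w, p2, "series"),
    scpsetnc = pse_composition(seq, 3L, lambda, w, p3, "series")))
  fv_concat(parts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

prefix_fv <- function(fv, prefix)
  feature_vector(as.numeric(fv), paste0(prefix, names(fv)))

#' Run a featurization batch
#'
#' Reads the configured input, validates every record, computes the selected
#' feature families and writes one output row per valid record. Invalid
#' records are skipped with a logged reason; a summary line reports the
#' accounting (`rows written + skipped == records read`).
#'
#' @param config a `run_config` from [load_config()].
#' @return Invisibly, a list with `status` (0 iff at least one row was
#'   written), `written`, `skipped` and the output `path`.
#' @export
run_featurize <- function(config) {
  stopifnot(inherits(config, "run_config"))
  recs <- read_records(config)
  mols <- attr(recs, "mols")
  rows <- list(); ids <- character(0); skipped <- 0L
  for (i in seq_len(nrow(recs))) {
    fv <- tryCatch({
      switch(config$kind,
        protein = featurize_protein(recs$payload[i], config$families, config$params),
        dna = featurize_dna(recs$payload[i], config$families, config$params),
        chem = {
          mol <- if (!is.null(mols)) mols[[as.integer(recs$payload[i])]]
                 else parse_structure(recs$payload[i], "smiles")
          if (isTRUE(config$standardize)) mol <- standardize_structure(mol)
          if ("all" %in% config$families) all_descriptors(mol)
          else fv_concat(lapply(config$families, function(g) descriptor_group(mol, g)))
        },
        fingerprint = {
          mol <- if (!is.null(mols)) mols[[as.integer(recs$payload[i])]]
                 else parse_structure(recs$payload[i], "smiles")
          if (isTRUE(config$standardize)) mol <- standardize_structure(mol)
          fv_concat(lapply(config$families, function(f) {
            fp <- fingerprint(mol, f)
            feature_vector(as.numeric(fp), paste0(f, ".", seq_along(fp)))
          }))
        })
    }, error = function(e) {
      message("skipping record '", recs$id[i], "': ", conditionMessage(e))
      NULL
    })
    if (is.null(fv)) { skipped <- skipped + 1L; next }
    rows[[length(rows) + 1L]] <- fv
    ids <- c(ids, recs$id[i])
  }
  message(sprintf("featurized %d record(s), skipped %d of %d",
                  length(rows), skipped, nrow(recs)))
  if (length(rows) == 0L)
    return(invisible(list(status = 1L, written = 0L, skipped = skipped,
                          path = config$output)))
  write_table(rows, format = config$out_format, path = config$output,
              ids = ids, digits = config$digits)
  invisible(list(status = 0L, written = length(rows), skipped = skipped,
                 path = config$output))
}

#' Write feature rows to a delimited or JSON table
#'
#' All rows must share an identical feature-name header. CSV/TSV output has
#' an `id` column followed by one column per feature; JSON output is a list
#' of objects. Values are serialized with a fixed number of significant
#' digits so identical runs give byte-identical files.
#'
#' @param rows list of [feature_vector()]s with identical names.
#' @param format `"csv"`, `"tsv"` or `"json"`.
#' @param path output file; `NULL` writes to stdout.
#' @param ids row identifiers (default `row1..rowN`).
#' @param digits significant digits for serialization.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, format = c("csv", "tsv", "json"), path = NULL,
                        ids = NULL, digits = 6L) {
  format <- match.arg(format)
  if (length(rows) == 0L) stop("no rows to write")
  nms <- names(rows[[1L]])
  for (i in seq_along(rows))
    if (!identical(names(rows[[i]]), nms))
      stop("heterogeneous feature rows: row ", i,
           " does not share the common header")
  if (is.null(ids)) ids <- paste0("row", seq_along(rows))
  fmt_num <- function(x) formatC(signif(x, digits), format = "g",
                                 digits = digits)
  con <- if (is.null(path)) stdout() else file(path, "w")
  if (!is.null(path)) on.exit(close(con))
  if (format == "json") {
    objs <- lapply(seq_along(rows), function(i)
      c(list(id = ids[i]),
        as.list(stats::setNames(signif(as.numeric(rows[[i]]), digits), nms))))
    writeLines(jsonlite::toJSON(objs, auto_unbox = TRUE, digits = NA), con)
  } else {
    sep <- if (format == "csv") "," else "\t"
    writeLines(paste(c("id", nms), collapse = sep), con)
    for (i in seq_along(rows))
      writeLines(paste(c(ids[i], fmt_num(as.numeric(rows[[i]]))),
                       collapse = sep), con)
  }
  invisible(path)
}

#' Featurize an interaction pair list
#'
#' Joins a two-column pair list against two per-molecule feature tables and
#' emits one combined interaction row per pair using [combine_same()] /
#' [combine_cross()].
#'
#' @param pairs data frame (or TSV path) with columns `id_a`, `id_b`.
#' @param table_a,table_b data frames (or CSV paths) whose first column is
#'   the molecule id, remaining columns numeric features.
#' @param mode `"same"` or `"cross"`.
#' @param strategy strategy name passed to the combiner.
#' @param ordering for same-type concat: `"both"`, `"ab"` or `"ba"`.
#' @return List of `pair_feature` rows (for `"both"`, ab and ba
#'   interleaved per pair).
#' @export
featurize_pairs <- function(pairs, table_a, table_b, mode = c("same", "cross"),
                            strategy = "concat", ordering = "both") {
  mode <- match.arg(mode)
  if (is.character(pairs))
    pairs <- utils::read.table(pairs, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  load_tab <- function(t) {
    if (is.character(t)) t <- utils::read.csv(t, stringsAsFactors = FALSE,
                                              check.names = FALSE)
    m <- as.matrix(t[, -1L, drop = FALSE])
    rownames(m) <- as.character(t[[1L]])
    storage.mode(m) <- "double"
    m
  }
  ta <- load_tab(table_a); tb <- load_tab(table_b)
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    ia <- as.character(pairs[[1L]][i]); ib <- as.character(pairs[[2L]][i])
    if (!ia %in% rownames(ta)) stop("pair id not in table_a: ", ia)
    if (!ib %in% rownames(tb)) stop("pair id not in table_b: ", ib)
    fa <- feature_vector(ta[ia, ]); fb <- feature_vector(tb[ib, ])
    if (mode == "same") {
      res <- combine_same(fa, fb, strategy, a_name = ia, b_name = ib)
      if (strategy == "concat") {
        if (ordering %in% c("both", "ab")) out[[length(out) + 1L]] <- res$ab
        if (ordering %in% c("both", "ba")) out[[length(out) + 1L]] <- res$ba
      } else out[[length(out) + 1L]] <- res
    } else {
      out[[length(out) + 1L]] <- combine_cross(fa, fb, strategy,
                                               t_name = ia, d_name = ib)
    }
  }
  out
}
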