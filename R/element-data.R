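# Per-element constants: atomic number, mass, Pauling electronegativity,
# covalent radius (A), van der Waals radius (A), static polarizability (A^3),
# metal flag. Organic-subset values drive descriptor weightings; metals are
# carried only so that pretreatment (metal-bond breaking, salt stripping)
# can see them.

ELEMENTS <- local({
  tab <- rbind(
    # sym    Z    mass     en    rcov  rvdw  polar  metal
    c("H",   1,   1.008,  2.20, 0.31, 1.20, 0.667, 0),
    c("B",   5,  10.811,  2.04, 0.85, 1.92, 3.030, 0),
    c("C",   6,  12.011,  2.55, 0.76, 1.70, 1.760, 0),
    c("N",   7,  14.007,  3.04, 0.71, 1.55, 1.100, 0),
    c("O",   8,  15.999,  3.44, 0.66, 1.52, 0.802, 0),
    c("F",   9,  18.998,  3.98, 0.57, 1.47, 0.557, 0),
    c("Si", 14,  28.086,  1.90, 1.11, 2.10, 5.380, 0),
    c("P",  15,  30.974,  2.19, 1.07, 1.80, 3.630, 0),
    c("S",  16,  32.065,  2.58, 1.05, 1.80, 2.900, 0),
    c("Cl", 17,  35.453,  3.16, 1.02, 1.75, 2.180, 0),
    c("Se", 34,  78.960,  2.55, 1.20, 1.90, 3.770, 0),
    c("Br", 35,  79.904,  2.96, 1.20, 1.85, 3.050, 0),
    c("I",  53, 126.904,  2.66, 1.39, 1.98, 5.350, 0),
    c("As", 33,  74.922,  2.18, 1.19, 1.85, 4.310, 0),
    c("Li",  3,   6.941,  0.98, 1.28, 1.82, 24.30, 1),
    c("Na", 11,  22.990,  0.93, 1.66, 2.27, 24.11, 1),
    c("Mg", 12,  24.305,  1.31, 1.41, 1.73, 10.60, 1),
    c("Al", 13,  26.982,  1.61, 1.21, 1.84, 6.800, 1),
    c("K",  19,  39.098,  0.82, 2.03, 2.75, 43.40, 1),
    c("Ca", 20,  40.078,  1.00, 1.76, 2.31, 22.80, 1),
    c("Mn", 25,  54.938,  1.55, 1.39, 2.05, 9.400, 1),
    c("Fe", 26,  55.845,  1.83, 1.32, 2.04, 8.400, 1),
    c("Co", 27,  58.933,  1.88, 1.26, 2.00, 7.500, 1),
    c("Ni", 28,  58.693,  1.91, 1.24, 1.97, 6.800, 1),
    c("Cu", 29,  63.546,  1.90, 1.32, 1.96, 6.200, 1),
    c("Zn", 30,  65.380,  1.65, 1.22, 2.01, 5.750, 1),
    c("Ag", 47, 107.868,  1.93, 1.45, 2.11, 7.200, 1),
    c("Sn", 50, 118.710,  1.96, 1.39, 2.17, 7.700, 1),
    c("Pt", 78, 195.084,  2.28, 1.36, 2.13, 6.500, 1),
    c("Au", 79, 196.967,  2.54, 1.36, 2.14, 5.800, 1),
    c("Hg", 80, 200.590,  2.00, 1.32, 2.23, 5.700, 1))
  d <- data.frame(symbol = tab[, 1],
                  Z = as.integer(tab[, 2]),
                  mass = as.numeric(tab[, 3]),
                  en = as.numeric(tab[, 4]),
                  rcov = as.numeric(tab[, 5]),
                  rvdw = as.numeric(tab[, 6]),
                  polarizability = as.numeric(tab[, 7]),
                  metal = as.logical(as.integer(tab[, 8])),
                  stringsAsFactors = FALSE)
  rownames(d) <- d$symbol
  d
})

element_prop <- function(symbols, prop, default = NA_real_) {
  v <- ELEMENTS[symbols, prop]
  v[is.na(v)] <- default
  v
}

is_metal <- function(symbols) {
  m <- ELEMENTS[symbols, "metal"]
  m[is.na(m)] <- TRUE  # unknown elements treated as metal-like for pretreatment
  m
}
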