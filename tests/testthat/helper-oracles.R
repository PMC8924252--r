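# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: masses are summed atom by atom from a separately
# transcribed table, and subformula enumeration is a plain recursive search.

# IUPAC 2021 monoisotopic masses, transcribed independently of the package's
# internal table (more digits, different source layout).
ORACLE_MASS <- c(
  H = 1.0078250319, C = 12.0000000, N = 14.0030740052, O = 15.9949146221,
  F = 18.9984031627, Na = 22.9897692820, P = 30.9737615120, S = 31.9720706912,
  Cl = 34.9688527100, K = 38.9637064864, Br = 78.9183376, I = 126.9044719
)

# Atom-by-atom brute-force summation.
oracle_mass <- function(formula_string) {
  if (formula_string == "") return(0)
  toks <- regmatches(formula_string,
                     gregexpr("[A-Z][a-z]?[0-9]*", formula_string))[[1]]
  total <- 0
  for (tk in toks) {
    el <- gsub("[0-9]", "", tk)
    n <- sub("^[A-Za-z]+", "", tk)
    n <- if (n == "") 1L else as.integer(n)
    for (i in seq_len(n)) total <- total + ORACLE_MASS[[el]]
  }
  total
}

# Exhaustive recursive subformula enumeration: all element-wise subformulas
# whose protonated mass matches the target within ppm_tol and whose RDBE is
# >= -0.5. Returns a sorted character vector of formula strings.
oracle_subformulas <- function(counts, target_mass, ppm_tol,
                               proton = 1.00727646) {
  els <- names(counts)
  out <- character(0)
  recurse <- function(i, current) {
    if (i > length(els)) {
      mass <- sum(mapply(function(e, n) ORACLE_MASS[[e]] * n, els, current))
      if (abs((mass + proton - target_mass) / target_mass * 1e6) <= ppm_tol) {
        g <- function(e) if (e %in% els) current[[which(els == e)]] else 0
        r <- g("C") + 1 + (g("N") + g("P")) / 2 -
          (g("H") + g("F") + g("Cl") + g("Br") + g("I")) / 2
        if (r >= -0.5) {
          v <- unlist(current)
          names(v) <- els
          v <- v[v > 0]
          hill <- c(intersect(c("C", "H"), names(v)),
                    sort(setdiff(names(v), c("C", "H"))))
          out <<- c(out, paste0(names(v[hill]),
                                ifelse(v[hill] == 1, "", v[hill]),
                                collapse = ""))
        }
      }
      return(invisible())
    }
    for (n in 0:counts[[i]]) recurse(i + 1, c(current, n))
  }
  recurse(1, list())
  sort(out)
}

# Random plausible formula as a named integer vector, <= max_atoms atoms.
random_formula <- function(max_atoms = 40) {
  repeat {
    f <- c(C = sample(3:12, 1), H = sample(4:18, 1), N = sample(0:2, 1),
           O = sample(0:4, 1), S = sample(0:1, 1))
    f <- f[f > 0]
    if (sum(f) <= max_atoms) return(f)
  }
}

# Small two-compound design used by several extraction tests.
tiny_design <- function(seed = 42, n = 3, gradient = 120, noise = 10,
                        jitter = 3, cv = 0.1, ...) {
  set.seed(seed)
  cms <- sim_compound_set(n, gradient_length = gradient)
  sim_design(cms, n_dilutions = 1, n_replicates = 1,
             gradient_length = gradient, ms1_interval = 2,
             mass_jitter_ppm = jitter, intensity_cv = cv,
             noise_peaks_per_spectrum = noise, seed = seed, ...)
}
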