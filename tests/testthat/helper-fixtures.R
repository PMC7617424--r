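# Shared fixture builders. Everything is constructed in code; the only
# on-disk fixtures are the bundled suture map and the reference region
# closure table.

tiny_map <- function() {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(c("suture,region,origin",
               "interfrontal,vault,neural_crest",
               "basispheno-presphenoid,cranial base,mesoderm",
               "parieto-squamosal,circum-meatal,boundary",
               "interpalatine,palate,neural_crest",
               "internasal,facial,neural_crest",
               "naso-frontal,cranio-facial,neural_crest"), path)
  read_suture_map(path)
}

# A fusion matrix built directly from a named score list
make_matrix <- function(scores, sutures) {
  m <- do.call(rbind, scores)
  colnames(m) <- sutures
  fusion_matrix(m)
}

write_matrix_csv <- function(lines, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = env)
  writeLines(lines, path)
  path
}

# Reference region-average closure percentages (full / placental /
# marsupial adult datasets), keyed by region ordinal.
reference_region_scores <- function(which) {
  reg <- utils::read.csv(system.file("extdata", "adult_region_closure.csv",
                                     package = "suturekit"))
  reg <- reg[reg$dataset == which, , drop = FALSE]
  reg$region <- match(reg$region, krogman_regions())
  reg
}

# All permutations of 1..n, as a list of integer vectors.
combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- combinat_perms(n - 1L)
  out <- list()
  for (p in sub) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}

# Brute-force Kendall tau-b by exhaustive pair classification; the
# independent oracle for the formula-based implementation.
brute_tau_b <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- sign(x[j] - x[i]); b <- sign(y[j] - y[i])
      if (a == 0) tx <- tx + 1
      if (b == 0) ty <- ty + 1
      if (a * b > 0) C <- C + 1
      if (a * b < 0) D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}
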