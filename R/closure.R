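#' Closure score of a collection of ordinal fusion scores
#'
#' The closure score is the weighted percentage of fusion across a set of
#' observations: each quarter-fused score (2) contributes 25%, half fused
#' (3) 50%, three-quarter fused (4) 75%, entirely fused (5) 100%, and
#' open (1) 0%, averaged over the non-missing observations. 0% means
#' fully open everywhere, 100% fully fused.
#'
#' @param scores Integer vector with values in 1..5; `NA` observations are
#'   excluded from the denominator.
#' @return Closure percentage in \[0, 100\].
#' @examples
#' closure_score(c(1, 2, 3, 4, 5))  # 50
#' @export
closure_score <- function(scores) {
  s <- scores[!is.na(scores)]
  if (!length(s)) stop("no observations: all scores missing")
  if (any(s < 1 | s > 5 | s != as.integer(s))) {
    stop("scores must be integers in 1..5")
  }
  n <- length(s)
  nk <- tabulate(s, nbins = 5L)
  100 * (0.25 * nk[2] + 0.5 * nk[3] + 0.75 * nk[4] + 1.0 * nk[5]) / n
}

closure_table <- function(df, level) {
  stopifnot(level %in% c("suture", "specimen", "species_stage", "region"))
  attr(df, "level") <- level
  class(df) <- c("closure_table", "data.frame")
  df
}

#' Per-suture closure scores
#'
#' Computes the closure score of each suture over a chosen set of
#' specimens (for example all adults, or a species' full ontogenetic
#' series), pooling that suture's column of the score matrix.
#'
#' @param matrix A `fusion_matrix`.
#' @param specimens Optional character vector of specimen ids (or logical
#'   vector over rows) selecting the specimens to pool; default all.
#' @return A `closure_table` (level `"suture"`) with columns `suture`,
#'   `closure_pct`, `n_obs`. Sutures with no observed cell in the
#'   selection are dropped with a warning.
#' @export
suture_closure_scores <- function(matrix, specimens = NULL) {
  m <- unclass(matrix)
  if (!is.null(specimens)) {
    if (is.logical(specimens)) specimens <- rownames(m)[specimens]
    missing_ids <- setdiff(specimens, rownames(m))
    if (length(missing_ids)) {
      stop("unknown specimen(s): ", paste(missing_ids, collapse = ", "))
    }
    m <- m[specimens, , drop = FALSE]
  }
  if (nrow(m) == 0L) stop("empty specimen selection")
  n_obs <- colSums(!is.na(m))
  if (any(n_obs == 0L)) {
    warning("suture(s) with no observations dropped: ",
            paste(colnames(m)[n_obs == 0L], collapse = ", "))
  }
  keep <- n_obs > 0L
  pct <- vapply(which(keep), function(j) closure_score(m[, j]), numeric(1))
  closure_table(data.frame(suture = colnames(m)[keep],
                           closure_pct = pct, n_obs = n_obs[keep],
                           row.names = NULL, stringsAsFactors = FALSE),
                "suture")
}

#' Per-specimen total closure scores
#'
#' The total suture closure score of each specimen, pooling all sutures
#' of that specimen's row. Specimens whose entire row is missing are
#' excluded and recorded on the result (attribute `excluded`).
#'
#' @param matrix A `fusion_matrix`.
#' @return A `closure_table` (level `"specimen"`) with columns
#'   `specimen`, `closure_pct`, `n_obs`.
#' @export
specimen_total_closure <- function(matrix) {
  m <- unclass(matrix)
  if (nrow(m) == 0L) stop("empty matrix")
  n_obs <- rowSums(!is.na(m))
  excluded <- rownames(m)[n_obs == 0L]
  keep <- n_obs > 0L
  pct <- vapply(which(keep), function(i) closure_score(m[i, ]), numeric(1))
  out <- closure_table(data.frame(specimen = rownames(m)[keep],
                                  closure_pct = pct, n_obs = n_obs[keep],
                                  row.names = NULL, stringsAsFactors = FALSE),
                       "specimen")
  attr(out, "excluded") <- excluded
  out
}

#' Species-by-stage average closure
#'
#' Arithmetic mean of specimen total closure scores within each
#' (species, developmental stage) cell. Cells with no specimens are
#' simply absent (e.g. a species that was assigned no juvenile).
#'
#' @param specimen_table A `closure_table` from [specimen_total_closure()].
#' @param meta Specimen metadata with `specimen_id`, `species`, `stage`.
#' @return A `closure_table` (level `"species_stage"`) with columns
#'   `species`, `stage`, `closure_pct`, `n_obs`.
#' @export
stage_averages <- function(specimen_table, meta) {
  d <- merge(specimen_table, meta[, c("specimen_id", "species", "stage")],
             by.x = "specimen", by.y = "specimen_id")
  d <- d[!is.na(d$stage) & d$stage != "", , drop = FALSE]
  agg <- stats::aggregate(closure_pct ~ species + stage, data = d, FUN = mean)
  n <- stats::aggregate(cbind(n_obs = closure_pct) ~ species + stage,
                        data = d, FUN = length)
  out <- merge(agg, n, by = c("species", "stage"))
  stage_lv <- c("F", "I", "J", "A")
  out <- out[order(out$species, match(out$stage, stage_lv)), , drop = FALSE]
  rownames(out) <- NULL
  closure_table(out, "species_stage")
}

#' Krogman-region average closure
#'
#' Per region, the unweighted mean of its member sutures' closure scores
#' (each suture counts once, however many specimens it pooled).
#'
#' @param suture_table A `closure_table` from [suture_closure_scores()].
#' @param suture_map A `suture_map` covering every suture in the table.
#' @return A `closure_table` (level `"region"`) with columns `region`
#'   (ordinal), `region_name`, `closure_pct`, `n_obs` (member suture
#'   count), one row per region 1-6.
#' @export
region_averages <- function(suture_table, suture_map) {
  unknown <- setdiff(suture_table$suture, suture_map$suture)
  if (length(unknown)) {
    stop("suture(s) missing from map: ", paste(unknown, collapse = ", "))
  }
  reg <- suture_map$region[match(suture_table$suture, suture_map$suture)]
  empty <- setdiff(1:6, reg)
  if (length(empty)) {
    stop("region(s) with no member sutures: ",
         paste(krogman_regions()[empty], collapse = ", "))
  }
  pct <- tapply(suture_table$closure_pct, reg, mean)
  n <- tapply(suture_table$closure_pct, reg, length)
  ids <- as.integer(names(pct))
  closure_table(data.frame(region = ids,
                           region_name = krogman_regions()[ids],
                           closure_pct = as.numeric(pct),
                           n_obs = as.integer(n),
                           row.names = NULL, stringsAsFactors = FALSE),
                "region")
}

#' Write a closure table as tidy CSV
#'
#' @param table A `closure_table`.
#' @param path Output path. Percentages are written at full precision;
#'   round at presentation time only.
#' @return `path`, invisibly.
#' @export
write_closure_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
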