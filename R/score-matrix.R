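#' Construct a fusion score matrix
#'
#' A fusion score matrix holds one ordinal fusion score per (specimen,
#' suture) cell: 1 fully open, 2 quarter fused, 3 half fused, 4
#' three-quarter fused, 5 entirely fused. Missing observations
#' (preservational damage, unscorable cells) are `NA`; they are distinct
#' from score 1, which the scoring convention also assigns to sutures
#' absent because a variably present bone is lacking.
#'
#' @param x Integer matrix with values in 1..5 or `NA`; rownames are
#'   specimen ids, colnames suture names.
#' @return A `fusion_matrix` object.
#' @export
fusion_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("fusion matrix needs specimen rownames and suture colnames")
  }
  bad <- !is.na(x) & (x < 1L | x > 5L)
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("score %d outside {1..5} at (%s, %s)",
                 x[bad][1], rownames(x)[ij[1]], colnames(x)[ij[2]]))
  }
  structure(x, class = c("fusion_matrix", "matrix", "array"))
}

#' Read a fusion score matrix from CSV
#'
#' The file has one row per specimen: a `specimen_id` column followed by
#' one column per suture, with cells in `1`..`5` or `?` for missing.
#' Columns are reordered to the suture map's order; a column naming a
#' suture not in the map is an error.
#'
#' @param path CSV path.
#' @param suture_map A `suture_map` from [read_suture_map()].
#' @return A `fusion_matrix` with `NA` in place of `?`.
#' @export
read_score_matrix <- function(path, suture_map) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0L) stop("no specimens: score matrix file is empty")
  if (names(df)[1] != "specimen_id") {
    stop("first column of a score matrix must be 'specimen_id'")
  }
  sutures <- names(df)[-1]
  unknown <- setdiff(sutures, suture_map$suture)
  if (length(unknown)) {
    stop("column(s) not present in suture map: ",
         paste(unknown, collapse = ", "))
  }
  specs <- df$specimen_id
  if (anyDuplicated(specs)) {
    stop("duplicate specimen_id: ", specs[duplicated(specs)][1])
  }
  m <- matrix(NA_integer_, nrow(df), length(sutures),
              dimnames = list(specs, sutures))
  for (j in seq_along(sutures)) {
    cell <- trimws(df[[j + 1L]])
    ok <- cell %in% c("1", "2", "3", "4", "5", "?")
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop(sprintf("invalid cell '%s' at (row %d '%s', column '%s'); allowed: 1-5 or ?",
                   cell[i], i, specs[i], sutures[j]))
    }
    m[, j] <- as.integer(replace(cell, cell == "?", NA))
  }
  ord <- intersect(suture_map$suture, sutures)
  fusion_matrix(m[, ord, drop = FALSE])
}

#' Write a fusion score matrix to CSV
#'
#' Inverse of [read_score_matrix()]: `NA` cells are written as `?`.
#'
#' @param matrix A `fusion_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(matrix, path) {
  chr <- apply(unclass(matrix), 2, function(v) ifelse(is.na(v), "?", as.character(v)))
  if (nrow(matrix) == 1L) chr <- matrix(chr, nrow = 1L, dimnames = dimnames(matrix))
  df <- data.frame(specimen_id = rownames(matrix), chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply the absent-bone scoring rule
#'
#' Sutures that do not exist because a variably present bone (e.g. the
#' jugal) is lacking are, by convention, scored 1 (open). This sets every
#' listed cell to 1. Cells that previously carried a known score other
#' than 1 are remembered on the result (attribute `absent_overrides`) so
#' [validate_dataset()] can flag them.
#'
#' @param matrix A `fusion_matrix`.
#' @param absences Data frame (or 2-column matrix) with columns
#'   `specimen`, `suture` naming the absent-bone cells.
#' @return The modified `fusion_matrix`.
#' @export
apply_absent_bone_rule <- function(matrix, absences) {
  absences <- as.data.frame(absences, stringsAsFactors = FALSE)
  if (nrow(absences) == 0L) return(matrix)
  names(absences)[1:2] <- c("specimen", "suture")
  bad_s <- !absences$specimen %in% rownames(matrix)
  bad_u <- !absences$suture %in% colnames(matrix)
  if (any(bad_s | bad_u)) {
    i <- which(bad_s | bad_u)[1]
    stop(sprintf("absence coordinate (%s, %s) not in matrix",
                 absences$specimen[i], absences$suture[i]))
  }
  idx <- cbind(match(absences$specimen, rownames(matrix)),
               match(absences$suture, colnames(matrix)))
  prior <- matrix[idx]
  overridden <- !is.na(prior) & prior != 1L
  matrix[idx] <- 1L
  prev <- attr(matrix, "absent_overrides")
  ov <- absences[overridden, c("specimen", "suture"), drop = FALSE]
  ov$prior_score <- prior[overridden]
  attr(matrix, "absent_overrides") <- unique(rbind(prev, ov))
  matrix
}

#' Ontogenetic ordering of specimens within species
#'
#' Orders each species' specimens from youngest to oldest by ascending
#' centroid size, the dataset's continuous developmental-age proxy.
#'
#' @param meta Specimen metadata data frame with `specimen_id`, `species`,
#'   and `centroid_size` columns.
#' @return Named list, one character vector of specimen ids per species.
#' @export
ontogenetic_order <- function(meta) {
  split_meta <- split(meta, meta$species)
  lapply(split_meta, function(d) d$specimen_id[order(d$centroid_size)])
}

#' Interpolate missing scores along ontogenetic series
#'
#' Within each species' ordered ontogenetic series, a `?` cell flanked by
#' known scores is replaced by the mean of the nearest known neighbours;
#' e.g. a series scoring 2, ?, 4 becomes 2, 3, 4. Runs of consecutive
#' missing cells all take the same flanking pair. Half-integer means are
#' rounded toward the lower (more open) score, conservative with respect
#' to claiming fusion. Missing cells at the start or end of a series
#' cannot be interpolated; they are left missing and reported on the
#' result (attribute `unfilled`).
#'
#' @param matrix A `fusion_matrix`.
#' @param ontogenetic_order Named list from [ontogenetic_order()]:
#'   specimen ids per species, youngest to oldest.
#' @return The interpolated `fusion_matrix`.
#' @export
interpolate_unknowns <- function(matrix, ontogenetic_order) {
  unfilled <- list()
  for (sp in names(ontogenetic_order)) {
    ids <- ontogenetic_order[[sp]]
    miss <- setdiff(ids, rownames(matrix))
    if (length(miss)) {
      stop("ontogenetic order names specimen(s) not in matrix: ",
           paste(miss, collapse = ", "))
    }
    rows <- match(ids, rownames(matrix))
    for (j in seq_len(ncol(matrix))) {
      v <- matrix[rows, j]
      if (!anyNA(v)) next
      known <- which(!is.na(v))
      for (i in which(is.na(v))) {
        lo <- known[known < i]
        hi <- known[known > i]
        if (length(lo) && length(hi)) {
          a <- v[max(lo)]; b <- v[min(hi)]
          matrix[rows[i], j] <- as.integer(floor((a + b) / 2))
        } else {
          unfilled[[length(unfilled) + 1L]] <-
            data.frame(species = sp, specimen = ids[i],
                       suture = colnames(matrix)[j],
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  attr(matrix, "unfilled") <-
    if (length(unfilled)) do.call(rbind, unfilled) else
      data.frame(species = character(), specimen = character(),
                 suture = character(), stringsAsFactors = FALSE)
  matrix
}

#' Validate a fusion dataset
#'
#' Pure report, never an error: lists specimens without metadata, residual
#' missing cells, per-species ontogenetic monotonicity violations (a
#' suture's score decreasing with age -- recorded as intraspecific
#' variation, not corrected), species with fewer than two specimens, and
#' any absent-bone overrides of previously scored cells.
#'
#' @param matrix A `fusion_matrix`.
#' @param suture_map A `suture_map`.
#' @param meta Specimen metadata data frame.
#' @return A `validation_report` list.
#' @export
validate_dataset <- function(matrix, suture_map, meta) {
  no_meta <- setdiff(rownames(matrix), meta$specimen_id)

  miss <- which(is.na(unclass(matrix)), arr.ind = TRUE)
  residual_missing <- data.frame(
    specimen = rownames(matrix)[miss[, 1]],
    suture = colnames(matrix)[miss[, 2]],
    stringsAsFactors = FALSE)

  counts <- table(meta$species[meta$specimen_id %in% rownames(matrix)])
  small_species <- names(counts)[counts < 2]

  ord <- ontogenetic_order(meta[meta$specimen_id %in% rownames(matrix), ,
                                drop = FALSE])
  viol <- list()
  for (sp in names(ord)) {
    rows <- match(ord[[sp]], rownames(matrix))
    for (j in seq_len(ncol(matrix))) {
      v <- matrix[rows, j]
      v <- v[!is.na(v)]
      if (length(v) >= 2 && any(diff(v) < 0)) {
        viol[[length(viol) + 1L]] <- data.frame(
          species = sp, suture = colnames(matrix)[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  monotonicity <- if (length(viol)) do.call(rbind, viol) else
    data.frame(species = character(), suture = character(),
               stringsAsFactors = FALSE)

  rep <- list(
    specimens_without_metadata = no_meta,
    residual_missing = residual_missing,
    monotonicity_violations = monotonicity,
    small_species = small_species,
    absent_overrides = attr(matrix, "absent_overrides"))
  rep$n_issues <- length(no_meta) + nrow(residual_missing) +
    nrow(monotonicity) + length(small_species)
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Fusion dataset validation report\n")
  cat("  specimens without metadata:", length(x$specimens_without_metadata), "\n")
  cat("  residual missing cells:    ", nrow(x$residual_missing), "\n")
  cat("  monotonicity notes:        ", nrow(x$monotonicity_violations), "\n")
  cat("  species with <2 specimens: ", length(x$small_species), "\n")
  if (!is.null(x$absent_overrides) && nrow(x$absent_overrides)) {
    cat("  absent-bone overrides of scored cells:",
        nrow(x$absent_overrides), "\n")
  }
  invisible(x)
}
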