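#' Percent-of-adult centroid size
#'
#' Expresses each specimen's centroid size (CS) as a percentage of its
#' species' adult CS, the dataset's continuous developmental-age proxy,
#' and carries log CS (natural log) for size correlations. If a species
#' has several stage-A specimens the largest is the designated adult
#' (recorded on the result, attribute `multiple_adults`); specimens
#' larger than the designated adult exceed 100% and trigger a warning.
#'
#' @param meta Specimen metadata data frame with columns `specimen_id`,
#'   `species`, `stage`, `centroid_size` (and optionally `infraclass`,
#'   `known_age_days`).
#' @return A `size_records` data frame: `specimen_id`, `species`, `stage`,
#'   `centroid_size`, `pct_adult_cs`, `log_cs`.
#' @export
percent_adult_cs <- function(meta) {
  if (any(!is.na(meta$centroid_size) & meta$centroid_size <= 0)) {
    stop("centroid_size must be positive")
  }
  multiple <- character()
  designated <- vapply(split(meta, meta$species), function(d) {
    a <- d[!is.na(d$stage) & d$stage == "A", , drop = FALSE]
    if (nrow(a) == 0L) {
      stop("species with no designated adult: ", d$species[1])
    }
    if (nrow(a) > 1L) multiple <<- c(multiple, d$species[1])
    a$specimen_id[which.max(a$centroid_size)]
  }, character(1))
  adult_cs <- meta$centroid_size[match(designated, meta$specimen_id)]
  names(adult_cs) <- names(designated)
  pct <- 100 * meta$centroid_size / adult_cs[meta$species]
  pct[meta$specimen_id %in% designated] <- 100  # exact, by definition
  over <- !is.na(pct) & pct > 100
  if (any(over)) {
    warning(sum(over), " specimen(s) larger than the designated adult ",
            "(>100% adult CS): ",
            paste(meta$specimen_id[over], collapse = ", "))
  }
  out <- data.frame(specimen_id = meta$specimen_id,
                    species = meta$species,
                    stage = meta$stage,
                    centroid_size = meta$centroid_size,
                    pct_adult_cs = as.numeric(pct),
                    log_cs = log(meta$centroid_size),
                    stringsAsFactors = FALSE)
  attr(out, "multiple_adults") <- unique(multiple)
  attr(out, "designated_adults") <- designated
  class(out) <- c("size_records", "data.frame")
  out
}

#' Assign discrete age categories
#'
#' Fills developmental stages F (foetal), I (infant), J (juvenile), A
#' (adult) from museum labels plus size-based rules:
#' (i) given F/I/J/A labels are kept;
#' (ii) an unlabelled marsupial specimen with a known age below 20 days
#'     becomes F;
#' (iii) within each species that has no juvenile yet, if more than one
#'     non-adult exceeds 95% of adult centroid size, all of them become
#'     J; otherwise the largest of the species' infants becomes J --
#'     unless the species has only a single infant, in which case no
#'     juvenile is assigned;
#' (iv) specimens that remain unlabelled are left unassigned and listed
#'     on the result (attribute `unassigned`).
#'
#' The procedure is deterministic and idempotent: reapplying it to its
#' own output changes nothing.
#'
#' @param meta Specimen metadata (see [percent_adult_cs()]).
#' @param size_records A `size_records` table from [percent_adult_cs()].
#' @return `meta` with an updated `stage` column.
#' @export
assign_age_categories <- function(meta, size_records) {
  stage <- meta$stage
  stage[!is.na(stage) & stage == ""] <- NA
  pct <- size_records$pct_adult_cs[match(meta$specimen_id,
                                         size_records$specimen_id)]

  # (ii) marsupial foetal rule, only where a known age is present
  if (!is.null(meta$known_age_days) && !is.null(meta$infraclass)) {
    fill <- is.na(stage) & meta$infraclass == "marsupial" &
      !is.na(meta$known_age_days) & meta$known_age_days < 20
    stage[fill] <- "F"
  }

  # (iii)/(iv) juvenile assignment per species
  for (sp in unique(meta$species)) {
    rows <- which(meta$species == sp)
    st <- stage[rows]
    if (any(!is.na(st) & st == "J")) next      # idempotence: J already set
    nonadult <- rows[is.na(st) | st != "A"]
    big <- nonadult[!is.na(pct[nonadult]) & pct[nonadult] > 95]
    if (length(big) > 1L) {
      stage[big] <- "J"
    } else {
      infants <- rows[!is.na(st) & st == "I"]
      if (length(infants) > 1L) {
        stage[infants[which.max(pct[infants])]] <- "J"
      }
    }
  }

  meta$stage <- stage
  attr(meta, "unassigned") <- meta$specimen_id[is.na(stage)]
  meta
}

#' Spearman correlation of closure with skull size
#'
#' Rank correlation between total suture closure and log centroid size,
#' across all specimens, within each species, or over adults only.
#' Groups with fewer than three paired observations are skipped with a
#' message. Because Spearman's rho is rank-based, the log transform (or
#' any strictly increasing transform) of CS cannot change rho.
#'
#' @param specimen_closure A `closure_table` from
#'   [specimen_total_closure()].
#' @param size_records A `size_records` table (carries species and stage).
#' @param grouping `"overall"`, `"per_species"`, or `"adults_only"`.
#' @return A `correlation_results` data frame: `group`, `rho`, `p`, `n`.
#' @export
spearman_closure_size <- function(specimen_closure, size_records,
                                  grouping = c("overall", "per_species",
                                               "adults_only")) {
  grouping <- match.arg(grouping)
  d <- merge(specimen_closure, size_records,
             by.x = "specimen", by.y = "specimen_id")
  if (grouping == "adults_only") {
    d <- d[!is.na(d$stage) & d$stage == "A", , drop = FALSE]
  }
  groups <- if (grouping == "per_species") split(d, d$species) else
    stats::setNames(list(d), grouping)

  rows <- lapply(names(groups), function(g) {
    dd <- groups[[g]]
    dd <- dd[!is.na(dd$closure_pct) & !is.na(dd$log_cs), , drop = FALSE]
    if (nrow(dd) < 3L) {
      message("group '", g, "' skipped: fewer than 3 paired observations")
      return(NULL)
    }
    ct <- suppressWarnings(stats::cor.test(dd$closure_pct, dd$log_cs,
                                           method = "spearman"))
    data.frame(group = g, rho = unname(ct$estimate), p = ct$p.value,
               n = nrow(dd), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(group = character(), rho = numeric(), p = numeric(),
                      n = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("correlation_results", "data.frame")
  out
}

#' One-way ANOVA of suture closure by embryonic origin
#'
#' Tests whether the tissue origin of a suture's articulating bones
#' (neural crest, mesoderm, or boundary) influences its degree of
#' fusion: a one-way fixed-effects ANOVA of per-suture closure scores on
#' the origin factor.
#'
#' @param suture_scores A `closure_table` at suture level.
#' @param suture_map A `suture_map` supplying each suture's origin.
#' @return An `anova_result` list: `f_stat`, `df_between`, `df_within`,
#'   `p`.
#' @export
anova_by_origin <- function(suture_scores, suture_map) {
  origin <- suture_map$origin[match(suture_scores$suture, suture_map$suture)]
  if (anyNA(origin)) {
    stop("suture(s) missing from map: ",
         paste(suture_scores$suture[is.na(origin)], collapse = ", "))
  }
  sizes <- table(origin)
  if (sum(sizes >= 2) < 2) {
    stop("need at least two origin groups with at least two sutures each")
  }
  y <- suture_scores$closure_pct
  if (stats::var(y) == 0) {
    stop("degenerate: all closure scores identical, F undefined")
  }
  fit <- stats::aov(y ~ factor(origin))
  tab <- summary(fit)[[1]]
  structure(list(f_stat = tab[["F value"]][1],
                 df_between = tab[["Df"]][1],
                 df_within = tab[["Df"]][2],
                 p = tab[["Pr(>F)"]][1]),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4f, p = %.4g\n",
              x$df_between, x$df_within, x$f_stat, x$p))
  invisible(x)
}
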