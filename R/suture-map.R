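#' Krogman region names
#'
#' The six classical anatomical suture groupings, in the order Krogman
#' proposed they fuse: vault (1), cranial base (2), circum-meatal (3),
#' palate (4), facial (5), cranio-facial (6).
#'
#' @return Character vector of length 6, names of the regions in Krogman
#'   order; positions give the region ordinals.
#' @export
krogman_regions <- function() {
  c("vault", "cranial base", "circum-meatal", "palate", "facial",
    "cranio-facial")
}

# Normalize region labels (names, common synonyms, or integers 1-6) to the
# region ordinal. Returns NA for unrecognized labels.
normalize_region <- function(x) {
  x <- as.character(x)
  out <- suppressWarnings(as.integer(x))
  chr <- is.na(out)
  if (any(chr)) {
    key <- tolower(trimws(x[chr]))
    key <- gsub("[_ ]+", " ", key)
    key <- gsub(" *\\([0-9]\\) *$", "", key)   # tolerate "vault (1)" style
    lut <- c(
      "vault" = 1L, "cranial vault" = 1L,
      "cranial base" = 2L, "base" = 2L, "cranialbase" = 2L,
      "circum-meatal" = 3L, "circum meatal" = 3L, "circummeatal" = 3L,
      "palate" = 4L, "palatal" = 4L,
      "facial" = 5L,
      "cranio-facial" = 6L, "cranio facial" = 6L, "craniofacial" = 6L
    )
    out[chr] <- unname(lut[key])
  }
  out[!is.na(out) & (out < 1L | out > 6L)] <- NA_integer_
  out
}

valid_origins <- c("neural_crest", "mesoderm", "boundary")

#' Read a suture map
#'
#' Reads a CSV describing each scored suture: its name, its Krogman region
#' (given as an ordinal 1-6 or a region name such as "vault" or
#' "cranial base"), and the embryonic tissue origin of the articulating
#' bones (`neural_crest`, `mesoderm`, or `boundary` for interfaces between
#' bones of different origin).
#'
#' @param path Path to a CSV with header columns `suture,region,origin`.
#' @return A `suture_map` data frame with columns `suture` (character),
#'   `region` (integer 1-6), `region_name` (character), and `origin`.
#' @seealso [krogman_sutures()] for the bundled 31-suture map.
#' @export
read_suture_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("suture", "region", "origin")
  if (!all(need %in% names(df))) {
    stop("suture map must have columns: ", paste(need, collapse = ", "))
  }
  df$suture <- trimws(df$suture)
  dup <- df$suture[duplicated(df$suture)]
  if (length(dup)) {
    stop("duplicate suture name(s) in map: ", paste(unique(dup), collapse = ", "))
  }
  reg <- normalize_region(df$region)
  if (anyNA(reg)) {
    bad <- which(is.na(reg))[1]
    stop(sprintf("unknown Krogman region '%s' at row %d (suture '%s')",
                 df$region[bad], bad, df$suture[bad]))
  }
  orig <- gsub("[ -]+", "_", tolower(trimws(df$origin)))
  if (!all(orig %in% valid_origins)) {
    bad <- which(!orig %in% valid_origins)[1]
    stop(sprintf("unknown origin '%s' at row %d (suture '%s'); expected one of %s",
                 df$origin[bad], bad, df$suture[bad],
                 paste(valid_origins, collapse = ", ")))
  }
  out <- data.frame(suture = df$suture,
                    region = reg,
                    region_name = krogman_regions()[reg],
                    origin = orig,
                    stringsAsFactors = FALSE)
  class(out) <- c("suture_map", "data.frame")
  out
}

#' Bundled 31-suture Krogman map
#'
#' The 31 cranial sutures and synchondroses scored in the mammalian
#' comparative dataset, each assigned to one of the six Krogman regions.
#' The region assignments follow the classical region scheme; the
#' embryonic-origin column is a reconstruction from the standard mouse
#' neural-crest/mesoderm fate map of the articulating bones (frontal and
#' facial bones neural crest; parietal, occipital and basioccipital
#' elements mesoderm; interfaces between tissues marked `boundary`).
#'
#' @return A `suture_map` with 31 rows spanning all six regions.
#' @export
krogman_sutures <- function() {
  read_suture_map(system.file("extdata", "krogman_table1.csv",
                              package = "suturekit", mustWork = TRUE))
}
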