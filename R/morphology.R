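#' Leaf-morphology criteria for the four shrub birch species
#'
#' The published discriminating leaf characters: blade shape, leaf size
#' (length x width in cm) and teeth shape. Categories are stored as sets of
#' base terms so that partial descriptors ("orbicular", "rounded") match.
#'
#' @return data.frame, one row per species.
#' @export
species_trait_table <- function() {
  data.frame(
    species = c("Betula glandulosa", "Betula pumila",
                "Betula occidentalis", "Betula nana ssp. exilis"),
    blade = c("obovate-orbicular",
              "elliptic-obovate-orbicular",
              "ovate-rhombic-ovate",
              "orbiculate-reniform"),
    teeth = c("obtuse-rounded",
              "acute-obtuse-rounded",
              "long-sharp",
              "rounded"),
    margin = c("dentate-crenate", "crenate-dentate",
               "sharply/doubly-serrate", "deeply-crenate"),
    length_min = c(0.5, 2.5, 2.0, 0.5),
    length_max = c(3.0, 5.0, 5.8, 1.2),
    width_min = c(1.0, 1.0, 1.0, 0.5),
    width_max = c(2.5, 5.0, 4.5, 1.6),
    stringsAsFactors = FALSE)
}

split_terms <- function(x) {
  tolower(strsplit(x, "[-/,* ]+")[[1]])
}

known_blade <- c("obovate", "orbicular", "elliptic", "ovate", "rhombic",
                 "orbiculate", "reniform")
known_teeth <- c("obtuse", "rounded", "acute", "long", "sharp")

#' Match leaf traits against the species criteria
#'
#' A species is a candidate iff the blade-shape and teeth categories match
#' (non-empty overlap of base terms, so "orbicular" matches the
#' "obovate-orbicular" category) and leaf length and width fall inside the
#' species' published ranges (inclusive). The margin category, largely
#' overlapping between species, is not used for exclusion.
#'
#' @param blade blade-shape descriptor (e.g. "obovate-orbicular").
#' @param length_cm,width_cm leaf dimensions in cm (> 0).
#' @param teeth teeth-shape descriptor (e.g. "obtuse-rounded").
#' @param margin optional margin descriptor (recorded, not discriminating).
#' @return character vector of candidate species (possibly empty).
#' @export
match_species <- function(blade, length_cm, width_cm, teeth, margin = NULL) {
  stopifnot(length_cm > 0, width_cm > 0)
  bt <- split_terms(blade)
  tt <- split_terms(teeth)
  if (!all(bt %in% known_blade))
    stop("unknown blade category term(s): ",
         paste(setdiff(bt, known_blade), collapse = ", "))
  if (!all(tt %in% known_teeth))
    stop("unknown teeth category term(s): ",
         paste(setdiff(tt, known_teeth), collapse = ", "))
  tab <- species_trait_table()
  hit <- vapply(seq_len(nrow(tab)), function(i) {
    sb <- split_terms(tab$blade[i])
    st <- split_terms(tab$teeth[i])
    length(intersect(bt, sb)) > 0 &&
      length(intersect(tt, st)) > 0 &&
      length_cm >= tab$length_min[i] && length_cm <= tab$length_max[i] &&
      width_cm >= tab$width_min[i] && width_cm <= tab$width_max[i]
  }, TRUE)
  tab$species[hit]
}
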