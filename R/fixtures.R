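#' Canonical injury-module names and classes
#'
#' The liver and kidney injury-module panels used throughout the package
#' as naming fixtures for synthetic collections. Each module carries an
#' injury class: inflammation, proliferation, or degeneration. The liver
#' panel has 11 modules (4/3/4 per class), the kidney panel 8 (3/1/4).
#' Memberships are not shipped; they are user-supplied or synthetic.
#'
#' @param organ `"liver"` or `"kidney"`.
#' @return A data.frame with columns `module` and `class`, in canonical
#'   class-grouped order (inflammation, proliferation, degeneration).
#' @examples
#' injury_module_panel("liver")
#' table(injury_module_panel("kidney")$class)
#' @export
injury_module_panel <- function(organ = c("liver", "kidney")) {
  organ <- match.arg(organ)
  if (organ == "liver") {
    data.frame(
      module = c(
        "Cellular infiltration", "Fibrogenesis", "Hematopoiesis",
        "Single cell necrosis",
        "Bile duct proliferation", "Cellular foci", "Oval cell proliferation",
        "Anisonucleosis", "Cytoplasmic alteration", "Granular degeneration",
        "Nuclear alteration"
      ),
      class = rep(c("inflammation", "proliferation", "degeneration"),
                  times = c(4L, 3L, 4L)),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      module = c(
        "Cellular infiltration", "Fibrogenesis",
        "Intracytoplasmic inclusion body",
        "Hypertrophy",
        "Degeneration", "Dilatation", "Hyaline cast", "Necrosis"
      ),
      class = rep(c("inflammation", "proliferation", "degeneration"),
                  times = c(3L, 1L, 4L)),
      stringsAsFactors = FALSE
    )
  }
}

INJURY_CLASSES <- c("inflammation", "proliferation", "degeneration")
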