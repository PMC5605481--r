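#' Path to the real-data reproduction recipe
#'
#' The full re-analysis of the original sequencing study (SRA study SRP073090
#' against the *Termitomyces* sp. J132 reference) is not desk scale: the raw
#' data are multi-gigabyte and alignment takes hours. The installed plain-text
#' recipe documents the inputs, the external alignment step, the exact
#' [run_scan()] invocation and the expected outcome (about 5% recombinant
#' phased reads in the filtered heterokaryon).
#'
#' @return Path to the installed recipe file.
#' @examples
#' readLines(srp073090_recipe_path(), n = 5)
#' @export
srp073090_recipe_path <- function() {
  system.file("extdata", "srp073090_recipe.md", package = "recombiscan",
              mustWork = TRUE)
}
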