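#' Published nine-mutant reference panel summary
#'
#' A compiled summary of a published panel of nine long-lived *C. elegans*
#' mutants spanning the classical pathways of lifespan extension
#' (insulin/IGF-1 signaling, dietary restriction, reduced translation,
#' mitochondrial impairment, elevated mitochondrial ROS, reduced
#' chemosensation, and germ-line ablation): the reported percent lifespan
#' extension of each strain and its reported direction of response
#' (`increased` / `decreased` / `unchanged`) to six stressors -- heat,
#' chronic oxidative stress, acute oxidative stress, bacterial pathogens,
#' osmotic stress, and anoxia. The direction calls are compiled from the
#' per-assay outcomes reported in the article's main text; the article's own
#' summary table draws on additional supplementary time points, so
#' individual calls may differ from it.
#'
#' Useful as a worked example for [resistance_count()] and [linear_fit()]:
#' counting each strain's `increased` calls and regressing lifespan
#' extension on the count reproduces the qualitative headline result that
#' the number of stressors a mutant resists tracks the magnitude of its
#' lifespan extension.
#'
#' @return data.frame with columns `strain`, `lifespan_extension_pct` and one
#'   direction-call column per stressor.
#' @examples
#' panel <- reference_panel()
#' counts <- apply(panel[, -(1:2)], 1, function(x) sum(x == "increased"))
#' linear_fit(counts, panel$lifespan_extension_pct)
#' @export
reference_panel <- function() {
  path <- system.file("extdata", "reference_panel.tsv", package = "stresspan",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
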