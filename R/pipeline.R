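# End-to-end convenience driver: half minimization -> linker superposition
# merge -> staged refinement.

#' Model a ternary complex from two half-complexes
#'
#' Runs the full pipeline: each half is minimized with its linker free and
#' the binding poses restrained, the halves are merged by superposing their
#' linker copies, and the merged model goes through the staged refinement
#' (local clash rounds, PROTAC-only, unrestrained) with a final
#' residual-clash quality check.
#'
#' @param poi_half,e3_half `half_complex` objects carrying chemically
#'   identical linkers.
#' @param config a [min_config()].
#' @param skip_stages refinement stages to skip (see [refine_tc()]).
#' @return list with `tc` (refined `ternary_complex`) and `report`
#'   (`refinement_report`).
#' @examples
#' \donttest{
#' fx <- make_toy_tc(fixture_spec(seed = 7))
#' out <- model_ternary_complex(fx$poi_half, fx$e3_half)
#' out$report$qc_pass
#' }
#' @export
model_ternary_complex <- function(poi_half, e3_half, config = min_config(),
                                  skip_stages = character()) {
  poi_min <- minimize_half(poi_half, config)
  e3_min <- minimize_half(e3_half, config)
  tc <- superpose_and_merge(poi_min, e3_min)
  refine_tc(tc, config = config, skip_stages = skip_stages)
}
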