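#' Segment macular layer boundaries on one B-scan
#'
#' Sequential live-wire driver: boundaries are traced in
#' [segmentation_order] (strongest interfaces first), each on its own cost
#' image from [make_background]; ROI constraints referring to boundaries
#' that are not part of this run are dropped, the others use the traces
#' already obtained.
#'
#' @param image a [bscan].
#' @param anchors named list of open-mode [anchor_seq], one per label to
#'   trace.
#' @param config a `filter_config`.
#' @param band_pad vertical search-band padding (px) passed to
#'   [trace_boundary].
#' @return Named list of [oct_boundary], in the order requested.
#' @export
segment_macular <- function(image, anchors,
                            config = default_filter_config(),
                            band_pad = 40L) {
  labs <- names(anchors)
  for (lab in labs) .check_label(lab)
  config <- .prune_roi(config, labs)
  traced <- list()
  for (lab in segmentation_order(labs)) {
    cost <- make_background(image, lab, config, prior = traced)
    traced[[lab]] <- trace_boundary(cost, anchors[[lab]], lab, band_pad)
  }
  traced[labs]
}
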