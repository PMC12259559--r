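#' qPCR relative quantification against a reference gene
#'
#' Converts paired threshold-cycle (Ct) measurements into a relative copy
#' count on the standard 2^dCt scale: `2^(ct_reference - ct_target)`. A target
#' amplifying one cycle earlier than the reference (dCt = 1) therefore counts
#' as twice as abundant; equal cycles give exactly 1. Both arguments are
#' vectorized and recycled.
#'
#' @param ct_target Threshold cycle(s) of the target gene.
#' @param ct_reference Threshold cycle(s) of the reference gene (e.g.
#'   beta-actin).
#' @return Non-negative relative copy count(s).
#' @examples
#' relative_copy_count(22, 30)  # 2^8 = 256
#' @export
relative_copy_count <- function(ct_target, ct_reference) {
  if (!is.numeric(ct_target) || !is.numeric(ct_reference))
    stop("cycle values must be numeric", call. = FALSE)
  if (anyNA(ct_target) || anyNA(ct_reference) ||
      any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stop("cycle values must be finite", call. = FALSE)
  2^(ct_reference - ct_target)
}
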