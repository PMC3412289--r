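#' Published full-scale output reference values
#'
#' Output-side results reported for the full-scale network (23,500 CA1
#' cells driven through the detailed 1330-compartment neuron model, 20 pairs
#' per condition): the mean and SD of pairwise output Hamming distances and
#' of output spike counts, per pathway and condition. These are external
#' reference constants for comparison tables and documentation; the
#' threshold surrogate shipped here is *not* expected to reproduce them
#' quantitatively — only their qualitative structure (similar inputs give
#' smaller output distances than distinct inputs; distinct inputs land at
#' the chance level).
#'
#' @return data.frame with columns `pathway`, `condition`, `mean_hd`,
#'   `sd_hd`, `mean_spikes`, `sd_spikes`.
#' @examples
#' reference_output_hd()
#' @export
reference_output_hd <- function() {
  data.frame(
    pathway = c("CA3", "EC", "CA3", "EC"),
    condition = c("distinct", "distinct", "similar", "similar"),
    mean_hd = c(5688, 5696, 2931, 4315),
    sd_hd = c(56, 63, 50, 63),
    mean_spikes = c(3316, 3313, 3296, 3307),
    sd_spikes = c(52, 56, 43, 52)
  )
}
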