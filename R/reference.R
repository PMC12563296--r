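#' Published benchmark results for the full model
#'
#' Reference means reported for the method on its evaluation suite
#' (classification and partition-quality metrics per dataset), kept here for
#' side-by-side comparison with locally reproduced runs. The real citation
#' and social-network datasets require external downloads, so these numbers
#' are informational references, not assertions the package tests against;
#' the in-repo reproduction path is the LFR-style synthetic benchmark.
#'
#' @return data.frame with columns `dataset`, `accuracy`, `nmi`, `f1`,
#'   `ari`, `modularity`.
#' @export
reference_results <- function() {
  data.frame(
    dataset = c("CiteSeer", "CiteSeer-full", "Cora", "Cora-ML",
                "Facebook107", "Facebook414", "Facebook1912",
                "LFR-500", "LFR-1000"),
    accuracy = c(0.725, 0.936, 0.849, 0.850, 0.904, 0.873, 0.773, 0.952, 0.948),
    nmi      = c(0.464, 0.838, 0.669, 0.674, 0.789, 0.829, 0.713, 0.940, 0.978),
    f1       = c(0.586, 0.938, 0.836, 0.840, 0.575, 0.809, 0.326, 0.942, 0.757),
    ari      = c(0.477, 0.850, 0.687, 0.688, 0.832, 0.741, 0.692, 0.908, 0.940),
    modularity = c(0.708, 0.788, 0.689, 0.565, 0.476, 0.522, 0.462, 0.678, 0.770)
  )
}
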