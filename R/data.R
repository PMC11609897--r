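#' Published ADE loop-variant affinities
#'
#' ITC-measured dissociation constants of the Roquin-1 coreROQ domain for
#' HOMEZ-ADE hexaloop variants, with the corresponding sRBNS enrichment at
#' 50 nM protein. Used as simulator input for rank-order recovery
#' experiments and for affinity fold-change calculations.
#'
#' @return data.frame with columns `loop`, `srbns_E`, `kd_nM`, `kd_sd_nM`.
#' @export
#' @examples
#' a <- roquin_ade_affinities()
#' round(a$kd_nM[a$loop == "GUUAUA"] / a$kd_nM[a$loop == "GUUUUA"], 1)  # 2.6
roquin_ade_affinities <- function() {
  data.frame(
    loop = c("GUUUUA", "AUUUUA", "GUUAUA", "GUUUAA", "AUUUUC"),
    srbns_E = c(64.3, 6.7, 10.1, 6.4, 5.5),
    kd_nM = c(6.0, 28.9, 15.7, 39.1, 111.1),
    kd_sd_nM = c(1.0, 1.5, 4.6, 11.0, 28.2),
    stringsAsFactors = FALSE)
}
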