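#' Conservation value index per site
#'
#' CVI = sum over present species of log(a_i + 1) * e_i, where a_i is the
#' species' abundance at the site and e_i its conservation weight (1 for
#' unthreatened, 4 for class-II protected, 8 for class-I protected
#' species). The logarithm base defaults to 10, so a single individual
#' of an unthreatened species scores log10(2) = 0.301.
#'
#' @param cm site x species abundance matrix.
#' @param status named numeric weights over the community species, values
#'   in \{1, 4, 8\}.
#' @param log_base logarithm base (default 10).
#' @return named numeric vector of CVI values with a long-format
#'   per-species `breakdown` attribute (site, species, abundance, weight,
#'   term).
#' @export
cvi_profile <- function(cm, status, log_base = 10) {
  cm <- as.matrix(cm)
  if (any(cm < 0)) rip_stop("negative abundances")
  spp <- colnames(cm)
  if (!all(spp %in% names(status)))
    rip_stop("species missing a conservation weight: ",
             paste(setdiff(spp, names(status)), collapse = ", "))
  e <- status[spp]
  if (!all(e %in% c(1, 4, 8)))
    rip_stop("conservation weights must be in {1, 4, 8}")
  terms <- sweep(log(cm + 1, base = log_base), 2, e, "*")
  cvi <- rowSums(terms)
  pres <- which(cm > 0, arr.ind = TRUE)
  breakdown <- data.frame(
    site = rownames(cm)[pres[, 1]],
    species = spp[pres[, 2]],
    abundance = cm[pres],
    weight = unname(e[pres[, 2]]),
    term = terms[pres])
  breakdown <- breakdown[order(breakdown$site, breakdown$species), ]
  rownames(breakdown) <- NULL
  attr(cvi, "breakdown") <- breakdown
  cvi
}
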