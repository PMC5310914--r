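#' Relative increase in total mutation rate implied by a signature shift
#'
#' Suppose a sample carries M mutations of which N belong to a signature, so
#' the baseline proportion is p = N/M. If the signature gains dN mutations
#' while all other classes stay fixed, the new proportion is
#' q = (N + dN)/(M + dN) and the relative increase in the total rate is
#' `dN/M = (q - p)/(1 - q)`.
#'
#' @param p baseline signature proportion, in `[0, 1)`.
#' @param q new signature proportion, in `[0, 1)`.
#' @param percent return the value multiplied by 100.
#' @return the relative rate increase (negative if q < p).
#' @export
#' @examples
#' rate_increase(0.078, 0.088, percent = TRUE)  # about 1.1
rate_increase <- function(p, q, percent = FALSE) {
  if (any(p < 0) || any(p >= 1)) stop("p must be in [0, 1)")
  if (any(q < 0) || any(q >= 1)) stop("q must be in [0, 1); q = 1 is undefined")
  delta <- (q - p) / (1 - q)
  if (percent) 100 * delta else delta
}

#' Estimate the repeat-mutation fraction from sharing proportions
#'
#' Given the fraction of signature-class doubletons shared across a sample
#' split (`share_sig`) and the same fraction for all doubletons
#' (`share_all`), estimates the fraction of signature-class doubletons that
#' are repeat (recurrent) mutations. The `"excess"` method returns the plain
#' difference `share_sig - share_all`; the `"solve"` method models repeat
#' doubletons as always cross-split and returns
#' `(share_sig - share_all)/(1 - share_all)`.
#'
#' @param share_sig sharing proportion for the signature classes, in `[0,1]`.
#' @param share_all sharing proportion for all classes, in `[0,1]`, at most
#'   `share_sig`.
#' @param method `"excess"` (default) or `"solve"`.
#' @return estimated repeat fraction.
#' @export
#' @examples
#' repeat_share(0.177, 0.083)                    # 0.094
#' repeat_share(0.177, 0.083, method = "solve")  # about 0.1025
repeat_share <- function(share_sig, share_all, method = c("excess", "solve")) {
  method <- match.arg(method)
  if (share_sig < 0 || share_sig > 1 || share_all < 0 || share_all > 1) {
    stop("sharing proportions must be in [0, 1]")
  }
  if (share_all > share_sig) stop("share_all must not exceed share_sig")
  if (method == "excess") return(share_sig - share_all)
  if (share_all == 1) stop("share_all = 1 is undefined under the solve method")
  (share_sig - share_all) / (1 - share_all)
}
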