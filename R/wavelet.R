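# Coiflet analysis low-pass filters, orders 1-5 (filter length 6*order).
# Standard closed-form filter-bank constants; DC gain sqrt(2).
COIF_LO <- list(
  `1` = c(-1.5655728135791993e-02, -7.2732619512526450e-02,
          3.8486484686485778e-01, 8.5257202021160039e-01,
          3.3789766245748182e-01, -7.2732619512526450e-02),
  `2` = c(-7.2054944552034698e-04, -1.8232088709110323e-03,
          5.6114348193688343e-03, 2.3680171946847770e-02,
          -5.9434418646431092e-02, -7.6488599078280761e-02,
          4.1700518442323908e-01, 8.1272363544941351e-01,
          3.8611006682276289e-01, -6.7372554723725595e-02,
          -4.1464936786871777e-02, 1.6387336463203641e-02),
  `3` = c(-3.4599773197272781e-05, -7.0983302506379004e-05,
          4.6621695982040288e-04, 1.1175187708306303e-03,
          -2.5745176881367972e-03, -9.0079761367306242e-03,
          1.5880544863669452e-02, 3.4555027573297738e-02,
          -8.2301927106299827e-02, -7.1799821619154838e-02,
          4.2848347637737000e-01, 7.9377722262608719e-01,
          4.0517690240911824e-01, -6.1123390002972552e-02,
          -6.5771911281469364e-02, 2.3452696142077168e-02,
          7.7825964256727463e-03, -3.7935128643808019e-03),
  `4` = c(-1.7849909144933469e-06, -3.2596479400307510e-06,
          3.1229861599195265e-05, 6.2338854312787192e-05,
          -2.5997433712225682e-04, -5.8902022463321654e-04,
          1.2665610789256603e-03, 3.7514346971460866e-03,
          -5.6582838001308835e-03, -1.5211728187697211e-02,
          2.5082253337949612e-02, 3.9334422605589149e-02,
          -9.6220424535952642e-02, -6.6627472366817167e-02,
          4.3438603311435653e-01, 7.8223893442428261e-01,
          4.1530842700068227e-01, -5.6077319603569258e-02,
          -8.1266710249193727e-02, 2.6682304669604830e-02,
          1.6068947131575029e-02, -7.3461679362680507e-03,
          -1.6294924252267860e-03, 8.9231390253700297e-04),
  `5` = c(-9.6040101127678941e-08, -1.6237995172048338e-07,
          2.0612203985788783e-06, 3.7007277113394796e-06,
          -2.1270221672515614e-05, -4.1219861924265501e-05,
          1.4035632812373243e-04, 3.0185794166824478e-04,
          -6.3755892612588115e-04, -1.6616273039298788e-03,
          2.4315754425382886e-03, 6.7615202206204169e-03,
          -9.1595073386761625e-03, -1.9758391600965465e-02,
          3.2674799467057355e-02, 4.1287530472117834e-02,
          -1.0556315130733723e-01, -6.2037751574981960e-02,
          4.3798230665916338e-01, 7.7429362286032744e-01,
          4.2157126673075435e-01, -5.2046670253554764e-02,
          -9.1921588060086087e-02, 2.8169744270532353e-02,
          2.3408322118927783e-02, -1.0131584846900276e-02,
          -4.1593126275786402e-03, 2.1782943778456947e-03,
          3.5857774116175768e-04, -2.1208186206749400e-04))

#' Sub-band labels of the single-level 3D filter bank
#'
#' Character 1/2/3 of a label gives the filter (H = high-pass, L =
#' low-pass) applied along the x/y/z axis respectively.
#' @export
SUBBAND_LABELS <- c("HHH", "HHL", "HLH", "HLL", "LHH", "LHL", "LLH", "LLL")

#' Build a single-level undecimated Coiflet filter bank
#'
#' The bank is stationary (no decimation): every sub-band lives on the
#' input grid, so one tumor mask serves the original and all filtered
#' images. The high-pass filter is the quadrature mirror of the low-pass
#' analysis filter.
#'
#' @param order Coiflet order, 1 to 5 (default 1; filter length 6 * order).
#' @param mode boundary extension; only `"symmetric"` (half-sample,
#'   edge-repeating) is implemented.
#' @return A [WaveletBank-class].
#' @export
waveletBank <- function(order = 1L, mode = "symmetric") {
  order <- as.integer(order)
  if (!order %in% 1:5)
    gliostop("gliorad_invalid_argument", "Coiflet order must be in 1..5")
  if (mode != "symmetric")
    gliostop("gliorad_invalid_argument",
             "only symmetric boundary extension is implemented")
  lo <- COIF_LO[[as.character(order)]]
  n <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(n) - 1) # quadrature mirror filter
  new("WaveletBank", family = "coif", order = order, mode = mode,
      lo = lo, hi = hi)
}

#' Decompose a volume into the eight wavelet sub-bands
#'
#' Applies the separable low-/high-pass analysis pair along x, y and z
#' without decimation, returning the eight same-size sub-band images
#' HHH...LLL. Boundary handling is symmetric extension; the transform is
#' linear and deterministic.
#'
#' @param image a [VolumeImage-class]; each axis must be at least as long
#'   as the filter.
#' @param bank a [WaveletBank-class] (default Coiflet order 1).
#' @return Named list of eight [VolumeImage-class] objects in the order of
#'   [SUBBAND_LABELS].
#' @export
decomposeWavelet <- function(image, bank = waveletBank()) {
  arr <- image@values
  L <- length(bank@lo)
  if (any(dim(arr) < L))
    gliostop("gliorad_image_too_small",
             "image axis shorter than the filter length (%d)", L)
  filt <- list(H = bank@hi, L = bank@lo)
  fx <- lapply(filt, function(k) convAxis(arr, k, 1L))
  fxy <- list()
  for (a in c("H", "L"))
    for (b in c("H", "L"))
      fxy[[paste0(a, b)]] <- convAxis(fx[[a]], filt[[b]], 2L)
  out <- vector("list", 8L)
  names(out) <- SUBBAND_LABELS
  for (lab in SUBBAND_LABELS) {
    step3 <- convAxis(fxy[[substr(lab, 1, 2)]], filt[[substr(lab, 3, 3)]], 3L)
    out[[lab]] <- VolumeImage(step3, image@spacing, image@origin,
                              modality = image@modality, state = image@state)
  }
  out
}
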