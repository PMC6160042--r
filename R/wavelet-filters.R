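# Orthonormal scaling filters for the least-asymmetric Daubechies ("symlet")
# family, natural (synthesis) order, indexed by number of vanishing moments.
# One vanishing moment is the Haar filter.  Values are the standard published
# coefficients at double precision.
.symlet_filters <- list(
  `1` = c(0.70710678118654746, 0.70710678118654746),
  `2` = c(0.48296291314469025, 0.83651630373746899, 0.22414386804185735,
          -0.12940952255092145),
  `3` = c(0.33267055295095688, 0.80689150931333875, 0.45987750211933132,
          -0.13501102001039084, -0.085441273882241486, 0.035226291882100656),
  `4` = c(0.032223100604042702, -0.012603967262037833, -0.099219543576847216,
          0.29785779560527736, 0.80373875180591614, 0.49761866763201545,
          -0.02963552764599851, -0.075765714789273325),
  `5` = c(0.019538882735286728, -0.021101834024758855, -0.17532808990845047,
          0.016602105764522319, 0.63397896345821192, 0.72340769040242059,
          0.1993975339773936, -0.039134249302383094, 0.029519490925774643,
          0.027333068345077982),
  `6` = c(-0.007800708325034148, 0.0017677118642428036, 0.044724901770665779,
          -0.021060292512300564, -0.072637522786462516, 0.3379294217276218,
          0.787641141030194, 0.49105594192674662, -0.048311742585632998,
          -0.11799011114819057, 0.0034907120842174702, 0.015404109327027373),
  `7` = c(0.010268176708511255, 0.0040102448715336634, -0.10780823770381774,
          -0.14004724044296152, 0.28862963175151463, 0.76776431700316405,
          0.5361019170917628, 0.017441255086855827, -0.049552834937127255,
          0.067892693501372697, 0.03051551316596357, -0.01263630340325193,
          -0.0010473848886829163, 0.0026818145682578781),
  `8` = c(0.0018899503327594609, -0.0003029205147213668, -0.014952258337048231,
          0.0038087520138906151, 0.049137179673607506, -0.027219029917056003,
          -0.051945838107709037, 0.3644418948353314, 0.77718575170052351,
          0.48135965125837221, -0.061273359067658524, -0.14329423835080971,
          0.0076074873249176054, 0.031695087811492981, -0.00054213233179114812,
          -0.0033824159510061256),
  `9` = c(0.0010694900329086053, -0.00047315449868008311, -0.010264064027633142,
          0.0088592674934004842, 0.06207778930288603, -0.018233770779395985,
          -0.19155083129728512, 0.035272488035271894, 0.61733844914093583,
          0.717897082764412, 0.238760914607303, -0.054568958430834071,
          0.00058346274612580684, 0.03022487885827568, -0.01152821020767923,
          -0.013271967781817119, 0.00061978088898558676, 0.0014009155259146807),
  `10` = c(-0.00045932942100465878, 5.7036083618494284e-05,
           0.0045931735853118284, -0.00080435893201654491,
           -0.02035493981231129, 0.0057649120335819086, 0.049994972077376687,
           -0.0319900568824278, -0.035536740473817552, 0.38382676106708546,
           0.7695100370211071, 0.47169066693843925, -0.070880535783243853,
           -0.15949427888491757, 0.011609893903711381, 0.045927239231092203,
           -0.0014653825813050513, -0.0086412992770224222,
           9.5632670722894754e-05, 0.00077015980911449011)
)

#' Scaling filter of a least-asymmetric Daubechies wavelet
#'
#' Returns the orthonormal low-pass (scaling) filter for the least-asymmetric
#' Daubechies wavelet with the requested number of vanishing moments.  The
#' matching high-pass filter is the quadrature mirror of this one.
#'
#' @param vanishing_moments Integer between 1 and 10; 1 gives the Haar filter.
#' @return Numeric vector of filter coefficients (length
#'   `2 * vanishing_moments`).
#' @export
wavelet_filter <- function(vanishing_moments = 10) {
  key <- as.character(as.integer(vanishing_moments))
  h <- .symlet_filters[[key]]
  if (is.null(h)) {
    stop("vanishing_moments must be an integer between 1 and 10, got ",
         vanishing_moments)
  }
  h
}

# Quadrature mirror: g[m] = (-1)^(m-1) h[len - m + 1].
.qmf <- function(h) {
  len <- length(h)
  (-1)^(seq_len(len) - 1) * rev(h)
}
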