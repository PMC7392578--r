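# Closed-form Gaussian kernel derivatives. For g(d) = exp(-d^2 / (2 s^2)):
#   g'   = -(d/s^2) g
#   g''  = (d^2/s^4 - 1/s^2) g
#   g''' = (3 d/s^4 - d^3/s^6) g
gauss_deriv <- function(d, sigma, order) {
  g <- exp(-d^2 / (2 * sigma^2))
  switch(as.character(order),
    "0" = g,
    "1" = -(d / sigma^2) * g,
    "2" = (d^2 / sigma^4 - 1 / sigma^2) * g,
    "3" = (3 * d / sigma^4 - d^3 / sigma^6) * g,
    stop("order must be 0, 1, 2 or 3", call. = FALSE)
  )
}

# One half-profile of the foveal contour at distance d >= 0 from the pit
# center: baseline + wide parafoveal Gaussian - narrow inverted pit Gaussian.
# Order k > 0 gives the k-th derivative with respect to d (baseline drops).
dog_side_value <- function(baseline, a_pit, sigma_pit, a_para, sigma_para,
                           d, order = 0) {
  v <- a_para * gauss_deriv(d, sigma_para, order) -
    a_pit * gauss_deriv(d, sigma_pit, order)
  if (order == 0) v <- v + baseline
  v
}

# Integral of the half-profile from 0 to a (µm^2):
# int_0^a exp(-d^2/2s^2) dd = s * sqrt(2*pi) * (Phi(a/s) - 1/2).
dog_side_integral <- function(baseline, a_pit, sigma_pit, a_para, sigma_para,
                              a) {
  gauss_int <- function(amp, s) amp * s * sqrt(2 * pi) * (pnorm(a / s) - 0.5)
  baseline * a + gauss_int(a_para, sigma_para) - gauss_int(a_pit, sigma_pit)
}
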