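# Shared fixture builders: small morphologies and traces constructed in code.

soma_only_morphology <- function(diam = 15) {
  morphology(tibble::tibble(
    id = 1L, parent_id = NA_integer_, parent_pos = NA_real_,
    length = diam, diam_prox = diam, diam_dist = diam, region = "soma"
  ))
}

ball_stick_morphology <- function(len = 200, diam = 1, soma = 15) {
  morphology(tibble::tibble(
    id = c(1L, 2L), parent_id = c(NA_integer_, 1L),
    parent_pos = c(NA_real_, 1),
    length = c(soma, len), diam_prox = c(soma, diam),
    diam_dist = c(soma, diam), region = c("soma", "dendrite")
  ))
}

two_branch_morphology <- function(len = 100, d1 = 1, d2 = 1, soma = 15) {
  morphology(tibble::tibble(
    id = 1:3, parent_id = c(NA_integer_, 1L, 1L),
    parent_pos = c(NA_real_, 1, 1),
    length = c(soma, len, len),
    diam_prox = c(soma, d1, d2), diam_dist = c(soma, d1, d2),
    region = c("soma", "dendrite", "dendrite")
  ))
}

# flat current-clamp trace with one rectangular depolarization
square_pulse_trace <- function(baseline = -55, level = -30, dt = 0.1,
                               total_ms = 5000, t0 = 2000, t1 = 3000) {
  t <- seq(0, total_ms, by = dt)
  x <- rep(baseline, length(t))
  x[t >= t0 & t < t1] <- level
  new_trace(x, dt = dt, mode = "current_clamp")
}
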