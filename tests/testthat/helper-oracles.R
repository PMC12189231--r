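# Shared fixtures and independent oracles used across the suite.

# Reference parameter sets: mechanistic-family coefficients recovered by
# closed-form inversion from the published water-hyacinth traits.
ref <- reference_traits()
pn_ref <- invert_ye(ref$pn$alpha, ref$pn$pn_max, ref$pn$i_sat,
                    offset = ref$pn$rd)
j_ref <- invert_ye(ref$j$alpha, ref$j$j_max, ref$j$i_sat)

# Central finite difference, an oracle for derivatives.
central_diff <- function(f, x, h = 1e-4 * pmax(abs(x), 1)) {
  (f(x + h) - f(x - h)) / (2 * h)
}

# Plain bisection, an oracle for root finding (independent of uniroot).
bisect <- function(f, lo, hi, tol = 1e-10, maxit = 200) {
  flo <- f(lo)
  for (k in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (hi - lo < tol) break
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

# Grid argmax refined by golden-section search, an oracle for maxima.
grid_argmax <- function(f, lo, hi, n = 20001) {
  xs <- seq(lo, hi, length.out = n)
  ys <- f(xs)
  xs[which.max(ys)]
}

rel_err <- function(x, truth) abs(x - truth) / abs(truth)
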