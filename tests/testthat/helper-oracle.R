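# Independent oracles, written against the printed equations and the
# published pattern row layouts only -- deliberately sharing no code with
# the package implementation they check.

oracle_btv <- function(l, r) {
  10 * log10(sqrt((10^(l / 10))^2 + (10^(r / 10))^2))
}

oracle_ebtv <- function(ltv, ltd, rtv, rtd) {
  oracle_btv(ltv - ltd, rtv - rtd)
}

oracle_s <- function(btd, ebtv) {
  ifelse(btd >= 0, 100, pmax(0, 100 - 100 * abs(btd) / ebtv))
}

# 24-2 row layout (right-eye orientation), rows top to bottom:
# 4 / 6 / 8 / 9(nasal x=-27) / 9 / 8 / 6 / 4
oracle_grid_242 <- function(eye = "OD") {
  rows <- list(`21` = c(-9, -3, 3, 9), `15` = seq(-15, 15, 6),
               `9` = seq(-21, 21, 6), `3` = c(-27, seq(-21, 21, 6)))
  g <- do.call(rbind, lapply(names(rows), function(yy) {
    y <- as.numeric(yy)
    rbind(cbind(x = rows[[yy]], y = y), cbind(x = rows[[yy]], y = -y))
  }))
  g <- as.data.frame(g)
  if (eye == "OS") g$x <- -g$x
  g
}

# 30-2 row layout: 4 / 6 / 8 / 10 / 10 and mirror; eye-symmetric
oracle_grid_302 <- function(eye = "OD") {
  rows <- list(`27` = c(-9, -3, 3, 9), `21` = seq(-15, 15, 6),
               `15` = seq(-21, 21, 6), `9` = seq(-27, 27, 6),
               `3` = seq(-27, 27, 6))
  g <- do.call(rbind, lapply(names(rows), function(yy) {
    y <- as.numeric(yy)
    rbind(cbind(x = rows[[yy]], y = y), cbind(x = rows[[yy]], y = -y))
  }))
  as.data.frame(g)
}

# Naive per-location re-implementation of the full binocular derivation:
# union-frame merge, single-eye fallback, five-ring weighting, VFI.
# l / r are data frames (x, y, tv, td) for OS / OD; NA = not measured.
oracle_integrate <- function(l, r,
                             boundaries = c(5.7, 12.8, 19.0, 25.5),
                             weights = c(3.29, 1.28, 0.79, 0.57, 0.45)) {
  key <- function(d) paste(d$x, d$y)
  keys <- union(key(l), key(r))
  out <- data.frame(
    x = as.numeric(sub(" .*", "", keys)),
    y = as.numeric(sub(".* ", "", keys))
  )
  li <- match(keys, key(l))
  ri <- match(keys, key(r))
  res <- lapply(seq_along(keys), function(i) {
    ltv <- if (is.na(li[i])) NA else l$tv[li[i]]
    ltd <- if (is.na(li[i])) NA else l$td[li[i]]
    rtv <- if (is.na(ri[i])) NA else r$tv[ri[i]]
    rtd <- if (is.na(ri[i])) NA else r$td[ri[i]]
    hl <- is.finite(ltv) && is.finite(ltd)
    hr <- is.finite(rtv) && is.finite(rtd)
    if (hl && hr) {
      btv <- oracle_btv(ltv, rtv)
      ebtv <- oracle_ebtv(ltv, ltd, rtv, rtd)
    } else if (hl) {
      btv <- ltv; ebtv <- ltv - ltd
    } else if (hr) {
      btv <- rtv; ebtv <- rtv - rtd
    } else {
      return(c(NA, NA, NA, NA))
    }
    btd <- btv - ebtv
    c(btv, ebtv, btd, oracle_s(btd, ebtv))
  })
  res <- do.call(rbind, res)
  out$btv <- res[, 1]; out$ebtv <- res[, 2]
  out$btd <- res[, 3]; out$s <- res[, 4]
  out <- out[is.finite(out$s), ]
  ecc <- sqrt(out$x^2 + out$y^2)
  ring <- findInterval(ecc, boundaries) + 1
  out$w <- weights[ring]
  list(data = out, vfi = sum(out$s * out$w) / sum(100 * out$w) * 100)
}

# helpers shared by tests ---------------------------------------------

# monocular_field pair on a flat expected surface: tv = expected + td
flat_field <- function(eye, td_value, expected = 30, pattern = "24-2") {
  g <- vf_pattern(pattern, eye = eye)
  td <- rep(td_value, length.out = nrow(g))
  monocular_field(eye, pattern, g$x, g$y, tv = expected + td, td = td)
}

# random field pair: independent TDs in [-30, 5] per eye, flat surface
random_pair <- function(expected = 30, pattern = "24-2") {
  mk <- function(eye) {
    g <- vf_pattern(pattern, eye = eye)
    td <- runif(nrow(g), -30, 5)
    monocular_field(eye, pattern, g$x, g$y, tv = expected + td, td = td)
  }
  list(left = mk("OS"), right = mk("OD"))
}

field_df <- function(f) {
  data.frame(x = f$data$x, y = f$data$y, tv = f$data$tv, td = f$data$td)
}
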