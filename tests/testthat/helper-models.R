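# shared fixtures: small models, a toy two-layer medium for transport
# oracles, and an independent analog (non-weighted) Monte Carlo.

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# narrow vessel-free column of the standard layered skin
narrow_skin <- function(wavelength = 585, pig = "light", dz_dermis = 10) {
  build_layered_model(width_x = 40, dx = 10, dz_dermis = dz_dermis,
                      pigmentation = pigmentation(pig),
                      wavelength = wavelength)
}

# overwrite a model with a two-layer toy medium (boundary at z_split um);
# labels 1 and 3 carry the supplied coefficients
toy_two_layer <- function(p1, p2, z_split = 200, wavelength = 585) {
  m <- build_layered_model(width_x = 40, dx = 10, dz_dermis = 10,
                           pigmentation = pigmentation("light"),
                           wavelength = wavelength,
                           use_adjusted_dermis = FALSE)
  zc <- m$grid$z
  m$labels <- matrix(ifelse(zc < z_split, 1L, 3L), m$grid$nz, m$grid$nx)
  m$props <- m$props[m$props$label %in% c(1L, 3L), ]
  m$props[m$props$label == 1L, c("mu_a", "mu_s", "g")] <- as.list(p1)
  m$props[m$props$label == 3L, c("mu_a", "mu_s", "g")] <- as.list(p2)
  m
}

# analog Monte Carlo in planar layered geometry: explicit absorb-vs-
# scatter events, no weighting, no roulette.  Independent of the
# compiled kernel; used as the transport oracle.
analog_mc_planar <- function(mua, mus, g, z_edges_mm, n = 5000,
                             fresnel = TRUE, nrel = 1.37, seed = 5) {
  set.seed(seed)
  nlay <- length(mua)
  dep <- numeric(nlay); refl <- 0; trans <- 0
  rsp <- if (fresnel) ((nrel - 1) / (nrel + 1))^2 else 0
  for (i in seq_len(n)) {
    if (runif(1) < rsp) { refl <- refl + 1; next }
    z <- 1e-12; u <- c(0, 0, 1)
    repeat {
      iz <- max(1, min(nlay, findInterval(z, z_edges_mm)))
      mt <- mua[iz] + mus[iz]
      s <- rexp(1, mt)
      hit <- FALSE
      repeat {
        dzb <- if (u[3] > 1e-12) (z_edges_mm[iz + 1] - z) / u[3]
               else if (u[3] < -1e-12) (z_edges_mm[iz] - z) / u[3] else Inf
        if (s < dzb) break
        z <- z + u[3] * dzb + sign(u[3]) * 1e-12
        s <- s - dzb
        if (z <= 0 || z >= z_edges_mm[nlay + 1]) { hit <- TRUE; break }
        izn <- max(1, min(nlay, findInterval(z, z_edges_mm)))
        if (izn != iz) {
          s <- s * mt / (mua[izn] + mus[izn])
          iz <- izn; mt <- mua[iz] + mus[iz]
        }
      }
      if (hit && z <= 0) {
        ci <- -u[3]; sin_t <- nrel * sqrt(max(0, 1 - ci^2))
        r <- if (!fresnel) 0 else if (sin_t >= 1) 1 else {
          ct <- sqrt(1 - sin_t^2)
          rs <- (nrel * ci - ct) / (nrel * ci + ct)
          rp <- (nrel * ct - ci) / (nrel * ct + ci)
          0.5 * (rs^2 + rp^2)
        }
        if (runif(1) < r) { u[3] <- -u[3]; z <- 1e-12; next }
        refl <- refl + 1; break
      }
      if (hit && z >= z_edges_mm[nlay + 1]) { trans <- trans + 1; break }
      z <- z + u[3] * s
      iz <- max(1, min(nlay, findInterval(z, z_edges_mm)))
      if (runif(1) < mua[iz] / (mua[iz] + mus[iz])) { dep[iz] <- dep[iz] + 1; break }
      gg <- g[iz]
      ct <- if (abs(gg) < 1e-6) 2 * runif(1) - 1 else {
        t2 <- (1 - gg^2) / (1 - gg + 2 * gg * runif(1))
        (1 + gg^2 - t2^2) / (2 * gg)
      }
      st <- sqrt(max(0, 1 - ct^2)); ph <- 2 * pi * runif(1)
      if (abs(u[3]) > 0.99999) {
        u <- c(st * cos(ph), st * sin(ph), ct * sign(u[3]))
      } else {
        den <- sqrt(1 - u[3]^2)
        u <- c(st * (u[1] * u[3] * cos(ph) - u[2] * sin(ph)) / den + u[1] * ct,
               st * (u[2] * u[3] * cos(ph) + u[1] * sin(ph)) / den + u[2] * ct,
               -st * cos(ph) * den + u[3] * ct)
      }
      u <- u / sqrt(sum(u^2))
    }
  }
  list(dep = dep / n, refl = refl / n, trans = trans / n)
}
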