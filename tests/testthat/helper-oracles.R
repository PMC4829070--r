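# Independent fixed-step oracles for the CSDA transport operations, kept
# deliberately naive: forward Euler on dE/dz = -rho S(E) and trapezoidal
# accumulation of dt = dz / v(E), both at a fixed 1-um step.

# energy after depth z by 1-um forward Euler; returns 0 once below the floor
oracle_energy <- function(phantom, E0, z, step = 1e-3) {
  E <- E0
  zz <- 0
  floor_E <- 1
  while (zz < z) {
    h <- min(step, z - zz)
    m <- material_at(phantom, min(zz, phantom$length * (1 - 1e-12)))
    dEdz <- m$rho * stopping_power(m, E) / 10   # MeV/mm
    E <- E - dEdz * h
    zz <- zz + h
    if (E <= floor_E) return(0)
  }
  E
}

# stopping depth by the same Euler walk
oracle_range <- function(phantom, E0, step = 1e-3) {
  E <- E0
  zz <- 0
  while (E > 1 && zz < phantom$length) {
    m <- material_at(phantom, zz)
    dEdz <- m$rho * stopping_power(m, E) / 10
    E <- E - dEdz * step
    zz <- zz + step
  }
  zz
}

# transit time to depth z by 1-um trapezoid on 1/v along the Euler energies
oracle_transit <- function(phantom, E0, z, step = 1e-3) {
  E <- E0
  zz <- 0
  t <- 0
  inv_v <- 1 / velocity(E)
  while (zz < z) {
    h <- min(step, z - zz)
    m <- material_at(phantom, min(zz, phantom$length * (1 - 1e-12)))
    dEdz <- m$rho * stopping_power(m, E) / 10
    E2 <- max(E - dEdz * h, 1)
    inv_v2 <- 1 / velocity(E2)
    t <- t + h * (inv_v + inv_v2) / 2
    E <- E2
    inv_v <- inv_v2
    zz <- zz + h
  }
  t
}

# scene used by many spectrum tests: the reference cyclotron geometry with a
# deliberately sharp timing so depth structures stay resolvable
sharp_scene <- function(fixture = "wpe_homogeneous_230",
                        sigma_bunch = 0.05, sigma_det = 0.05) {
  fx <- make_fixture(fixture)
  fx$beam$sigma_bunch <- sigma_bunch
  fx$detector$sigma_det <- sigma_det
  fx
}

# local minima / maxima indices of a numeric vector
local_minima <- function(y) which(diff(sign(diff(y))) == 2) + 1
local_maxima <- function(y) which(diff(sign(diff(y))) == -2) + 1
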