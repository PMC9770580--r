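## shared fixtures: thermodynamics at the study temperature and small
## ground-truth landscapes for the Brownian-dynamics generator

thermo298 <- make_thermo(298.15)

## flat free energy, constant diffusion
flat_landscape <- function(d = 0.5, z_range = c(-3, 3)) {
  landscape(data.frame(z = z_range, value = c(0, 0)),
            data.frame(z = z_range, value = c(d, d)),
            z_range = z_range)
}

## double well on the monolayer-referenced domain of the 22-window scheme:
## wells near -1.4 and +1.0 nm, barrier of 5 kT (12.4 kJ/mol) between them
double_well_landscape <- function() {
  landscape(
    data.frame(z = c(-2.4, -2.0, -1.4, -0.8, -0.2, 0.4, 1.0, 1.6, 2.0),
               value = c(6, 2, 0, 6, 12.4, 6, 0.4, 0, 0)),
    data.frame(z = c(-2.4, 2.0), value = c(0.3, 0.3)),
    z_range = c(-2.6, 2.2))
}

## mild double well inside steep walls with five-fold varying diffusion;
## used for stationary-density checks of the generator
walled_landscape <- function() {
  landscape(
    data.frame(z = c(-1.2, -1.0, -0.6, -0.3, 0, 0.3, 0.6, 1.0, 1.2),
               value = c(60, 30, 0, 1, 2, 1, 0, 30, 60)),
    data.frame(z = c(-1.2, 0, 1.2), value = c(0.1, 0.25, 0.5)),
    z_range = c(-1.4, 1.4))
}

## harmonic (OU) window on a flat landscape
ou_window <- function(kf = 1000, d = 0.5, dt = 1e-5, n_steps = 2e6,
                      save_every = 20L, seed = 1L, center = 0) {
  simulate_window(flat_landscape(d), center, kf, thermo298, dt = dt,
                  n_steps = n_steps, save_every = save_every, seed = seed)
}

## a window made directly from given positions (uniform 1 ps grid)
window_from_positions <- function(positions, center = 0,
                                  force_constant = 1000, dt = 0.001) {
  umbrella_window(center, force_constant, dt * seq_along(positions),
                  positions)
}

## flat synthetic bilayer helper
flat_bilayer_frame <- function(n = 64, half = 2.0, box = c(6, 6, 10),
                               probe = c(3, 3, 7.5), z_noise = 0,
                               deformation = NULL, seed = 1L) {
  make_membrane_frames(n, half, z_noise = z_noise,
                       deformation = deformation,
                       probe_path = list(probe), box = box,
                       seed = seed)[[1L]]
}
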