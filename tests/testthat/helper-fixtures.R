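# Shared fixtures, built once per test session and cached. Grids are kept
# small (16^3 / 32^3) so the whole suite runs on one CPU in minutes.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

tiny_spec <- function() fixture("tiny_spec", function()
  phantom_spec(grid_shape = c(16, 16, 16), spacing = c(8, 8, 8),
               n_landmarks = 25L, noise_sigma = 0.01, seed = 7))

tiny_ref <- function() fixture("tiny_ref", function() make_reference(tiny_spec()))

desk_spec <- function() fixture("desk_spec", function()
  phantom_spec(grid_shape = c(32, 32, 32), spacing = c(4, 4, 4), seed = 7))

desk_ref <- function() fixture("desk_ref", function() make_reference(desk_spec()))

desk_series <- function() fixture("desk_series", function()
  make_phase_series(desk_spec()))

desk_geometry <- function() fixture("desk_geometry", function()
  projection_geometry(detector_shape = c(32, 32), detector_spacing = c(4, 4),
                      step_mm = 2))

desk_inter_fields <- function() fixture("desk_inter", function()
  make_interphase_fields(desk_series(),
                         demons_config(3, c(30, 20, 10),
                                       smoothing_sigma_mm = 3,
                                       max_step_mm = 4)))

# random smooth blob volume for projection / registration tests
blob_volume <- function(gs = c(32, 32, 32), sp = c(2, 2, 2),
                        centre_mm = (gs - 1) / 2 * sp, sigma_mm = 10) {
  g <- orthoreg:::grid_mm(gs, sp)
  volume3d(array(exp(-rowSums(sweep(g, 2, centre_mm)^2) / (2 * sigma_mm^2)), gs), sp)
}

# hard-histogram entropy on the same fixed [0,1] binning mi_term uses
hard_entropy01 <- function(x, n_bins = 32L) {
  i <- pmin(pmax(findInterval(x, seq(0, 1, length.out = n_bins + 1),
                              rightmost.closed = TRUE), 1L), n_bins)
  p <- tabulate(i, n_bins) / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

# constant-displacement backward field in mm
const_field <- function(gs, sp, u_mm) {
  a <- array(0, c(gs, 3))
  for (c3 in 1:3) a[, , , c3] <- u_mm[c3]
  deformation_field(a, sp, convention = "backward")
}
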