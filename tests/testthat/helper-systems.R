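# shared builders for small test systems

# frame with explicitly placed chains; coords0 is an nb x 3 matrix (0-based),
# chains laid out species by species in order
manual_frame <- function(coords0, species, model, box) {
  cfg <- run_config(species, model, box = box, temperatures = 1,
                    total_steps = 0, n_replicates = 1, seed = 1,
                    init_box = min(box))
  latmix:::new_frame(coords0, cfg, step = 0L)
}

# trajectory wrapper around a list of frames for analysis-function tests
manual_trajectory <- function(frames, species, model, box, temperature = 1) {
  cfg <- run_config(species, model, box = box, temperatures = temperature,
                    total_steps = 0, n_replicates = 1, seed = 1,
                    init_box = min(box))
  structure(list(frames = frames, frame_steps = seq_along(frames) - 1,
                 energy = data.frame(step = 0, energy = 0),
                 temperature = temperature, replicate = 1L, seed = 1L,
                 box = cfg$box,
                 system = list(species = species, model = model),
                 tables = cfg$tables),
            class = "mc_trajectory")
}

two_type_model <- function(eAA = -1, eAB = -1, eBB = -1, w_el = 0) {
  m <- matrix(c(eAA, eAB, eAB, eBB), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  interaction_model(m, w_el = w_el)
}

# straight chain along x starting at (x0, y0, z0)
straight_chain <- function(n, x0 = 0, y0 = 0, z0 = 0) {
  cbind(x0 + seq_len(n) - 1, rep(y0, n), rep(z0, n))
}
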