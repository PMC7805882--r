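# Small fixtures shared across the suite.  Everything is generated in code;
# sizes are kept small so the default run stays fast.

frontal_params <- function(bits = c(1, 0, 0, 1, 1, 0, 1, 0, 0, 0, 1, 0),
                           resolution = 64) {
  mid <- (resolution - 1) / 2
  tag_params(bits, yaw = 0, pitch = 0, roll = 0, center_row = mid,
             center_col = mid, radius = 0.38 * resolution)
}

# a handmade config whose effects are all exact identities
identity_hm_config <- function(resolution = 32) {
  handmade_config(resolution, alpha_range = c(0, 0), field_sd = 0, t_max = 0,
                  pyramid_scales = c(0, 0, 0), noise_range = c(0, 0),
                  max_spots = 0, spot_amp = c(0, 0))
}

# central finite difference of f at x (scalar displacement on element k)
num_grad <- function(f, x, k, eps = 1e-6) {
  x1 <- x; x1[k] <- x[k] + eps
  x2 <- x; x2[k] <- x[k] - eps
  (f(x1) - f(x2)) / (2 * eps)
}

# quick epochs-0 checkpoint (initialization only) at 16 px, direct mode
init_checkpoint <- function(seed = 42, resolution = 16) {
  cfg <- gan_config(resolution = resolution, batch_size = 4, epochs = 0,
                    batches_per_epoch = 1, seed = seed,
                    renderer_mode = "direct")
  corpus <- if (resolution == 16) hm_corpus(32, 16, test_hm16(), seed = 5)
            else hm_corpus(32, resolution, handmade_config(resolution), seed = 5)
  train_rendergan(cfg, corpus)
}

# gentler amplitudes: at 16 px a code cell is ~2 px, so the default
# effect strengths would break the recovery invariant
test_hm16 <- function() {
  handmade_config(16, pyramid_scales = c(0.5, 0.25, 0.12), field_sd = 0.25,
                  t_max = 0.2, spot_amp = c(0.1, 0.3),
                  noise_range = c(0.01, 0.05))
}
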