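# Shared fixtures, built in code at test time.

# Frequency table from a flat length-9 vector in row-major tree order.
ft9 <- function(v, n_miss = 0L) {
  freq_table(matrix(v, 3L, 3L, byrow = TRUE), n_miss = n_miss)
}

# A noiseless frequency table: category probabilities at `params`, scaled to
# `n` trials per tree. Only meaningful when n * probs are whole numbers or
# near-whole (rounding noise is then the only deviation).
noiseless_table <- function(params, n = 1000L) {
  probs <- category_probabilities(params)
  freq_table(round(probs * n))
}

# A small, valid trial log with one trial per response category.
tiny_trials <- function(id = "p001", group = "young") {
  trial_records(
    participant_id = id, group = group, block = 1L,
    item_id = sprintf("i%02d", 1:7),
    true_position = c("up", "up", "up", "down", "new", "new", "up"),
    item_response = c("old", "old", "new", "old", "old", "new", "miss"),
    source_response = c("up", "down", "none", "down", "up", "none", "none"),
    rt_item = c(1.2, 0.9, 1.1, 1.4, 0.8, 1.0, NA),
    rt_source = c(0.5, 0.7, NA, 0.6, 0.9, NA, NA)
  )
}

# Gaze stream of still epochs at given centers (list of c(x, y)) with
# `ms` samples each, joined by instantaneous jumps.
still_stream <- function(centers, ms = 300L, jitter = 0) {
  xs <- unlist(lapply(centers, function(c) rep(c[1L], ms)))
  ys <- unlist(lapply(centers, function(c) rep(c[2L], ms)))
  if (jitter > 0) {
    xs <- xs + stats::rnorm(length(xs), 0, jitter)
    ys <- ys + stats::rnorm(length(ys), 0, jitter)
  }
  data.frame(t_ms = seq_along(xs) - 1, x_deg = xs, y_deg = ys)
}

# Fixation data.frame straight from centroid coordinates.
fix_points <- function(cx, cy = rep(0, length(cx))) {
  data.frame(onset = seq_along(cx) * 1000, offset = seq_along(cx) * 1000 + 500,
             cx = cx, cy = cy, duration = rep(500, length(cx)))
}

# Polar sample of an ellipse with semi-axes a (horizontal), b (vertical).
ellipse_chart <- function(a, b, step = 2, offset = step / 2) {
  ang <- seq(offset, 360 - step + offset, by = step)
  th <- ang * pi / 180
  r <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  isopter_chart("right", "V1e", ang, r)
}
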