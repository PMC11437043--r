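# Shared fixtures, memoized so expensive renders/segmentations run once
# per test session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# A segmented synthetic wing (default study conditions).
fix_wing <- function(seed = 3) {
  memo(paste0("wing", seed), {
    w <- generate_wing(synth_config(seed = seed))
    list(raw = w$image, truth = w$truth,
         geom = segment_all(binarize(w$image)))
  })
}

# White digital disk of radius r on a dark background, as a wa_binary.
disk_binary <- function(r = 30, pad = 6) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  idx <- expand.grid(row = seq_len(n), col = seq_len(n))
  mask <- matrix((idx$row - ctr)^2 + (idx$col - ctr)^2 <= r^2, n, n)
  as_binary(mask)
}
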