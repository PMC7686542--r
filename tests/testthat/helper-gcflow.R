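## Shared fixtures: small partitions and generators used across tests.

# 12-ROI partition, two ROIs per network
tiny_partition <- function() {
  nets <- network_names()
  network_partition(paste0(rep(nets, each = 2), c("_a", "_b")),
                    rep(nets, each = 2))
}

# 4-ROI toy: a, b in MTL ("X"); c, d in DM ("Y")
toy_partition <- function() {
  network_partition(c("a", "b", "c", "d"), c("MTL", "MTL", "DM", "DM"))
}

# random nonnegative eff_conn over a partition
rand_ecm <- function(partition, seed = 1, subject_id = "s") {
  set.seed(seed)
  R <- length(partition$roi)
  m <- matrix(abs(rnorm(R * R)), R, R,
              dimnames = list(partition$roi, partition$roi))
  diag(m) <- 0
  eff_conn(m, subject_id)
}

# white-noise subject over a partition
noise_record <- function(partition, T = 100, seed = 1, group = "NC",
                         id = "noise") {
  set.seed(seed)
  m <- matrix(rnorm(T * length(partition$roi)), T,
              dimnames = list(NULL, partition$roi))
  subject_record(m, partition, id, group)
}
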