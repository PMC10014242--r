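# Small deterministic graphs used across tests.

make_complete <- function(n) {
  topology(n, t(utils::combn(n, 2)))
}

make_path <- function(n) {
  topology(n, cbind(seq_len(n - 1), seq_len(n - 1) + 1))
}

# node 1 is the hub
make_star <- function(n) {
  topology(n, cbind(1, 2:n))
}

make_empty <- function(n) {
  topology(n, NULL)
}

# sample a connected RGG of moderate density
random_connected_rgg <- function(n, seed, delta = 0.45) {
  generate_rgg(n, delta, seed = seed, connected = TRUE)
}
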