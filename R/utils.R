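# internal helpers

# round-half-away-from-zero; base round() rounds half to even, which would
# make edge counts like round(0.5 * 10) platform-surprising
.round_half_up <- function(x) floor(x + 0.5)

# deterministic child seeds below 2^31, derived from a master seed and a
# stream index; plain LCG-style mixing in double precision (exact up to 2^53)
.derive_seed <- function(seed, index) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  v <- (s * 48271 + as.numeric(index) * 16807 + 12345) %% 2147483647
  as.integer(v)
}

.as_igraph <- function(net) {
  stopifnot(is(net, "BinaryNetwork"))
  igraph::graph_from_adjacency_matrix(net@adjacency, mode = "undirected",
                                      diag = FALSE)
}

.new_network <- function(adjacency, density, provenance = list()) {
  mode(adjacency) <- "integer"
  new("BinaryNetwork", adjacency = adjacency, density = density,
      edgeCount = as.integer(sum(adjacency) / 2L), provenance = provenance)
}

# upper-triangle (row, col) index pairs in ascending (row-major) order,
# the documented deterministic tie-break order for thresholding
.upper_pairs <- function(n) {
  # (i < j) pairs ordered by row then column
  i <- sequence(seq_len(n - 1L))
  j <- rep.int(2:n, 1:(n - 1L))
  ord <- order(i, j)
  cbind(i[ord], j[ord])
}
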