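# shared helpers for building small in-code fixtures

# a size_matrix with all mass in the given bins (equal split), zero elsewhere
toy_matrix <- function(bins, mineral = "crocidolite", medium = "toy") {
  p <- numeric(32)
  p[bins] <- 100 / length(bins)
  size_matrix(mineral, medium, p)
}

# a dsr_table built directly from a 32-vector (NA allowed)
toy_dsr_table <- function(dsr, mineral = "crocidolite", source = "toy") {
  structure(list(mineral = mineral, exposure_source = source, dsr = dsr),
            class = "dsr_table")
}

all_fixture_ids <- function() {
  c("crocidolite/lung", "crocidolite/airborne_pooley",
    "crocidolite/dimensional_db", "amosite/lung",
    "amosite/airborne_pooley", "amosite/dimensional_db")
}

# exact interval-arithmetic tolerance for a DSR recomputed from percent
# frequencies printed at 2 d.p. and compared against a printed 2 d.p. ratio
printed_rounding_tol <- function(dsr, exposure_percent) {
  0.005 + 0.005 * (1 + dsr) / exposure_percent
}
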