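# Small fixtures built in code, shared across test files.

toy_counts <- function() {
  m <- matrix(c(5L, 3L, 2L,
                0L, 10L, 10L), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("otuA", "otuB", "otuC")))
  m
}

toy_table <- function() {
  otu_table(toy_counts(),
            taxonomy = c(otuA = "Eukaryota;Alveolata;Ciliophora",
                         otuB = "Eukaryota;Alveolata;Dinophyceae",
                         otuC = "Eukaryota;Stramenopiles;Diatomea"),
            sample_meta = data.frame(sample_id = c("s1", "s2"),
                                     season = c("wet", "dry"),
                                     longitude = c(116.3, 116.4),
                                     latitude = c(25.1, 25.2)))
}

# Y-shaped river: origin o, confluence c, two branch tips a (3 km) and b (4 km)
y_network <- function() {
  nodes <- data.frame(node = c("o", "c", "a", "b"),
                      longitude = c(116.30, 116.31, 116.32, 116.33),
                      latitude = c(25.10, 25.11, 25.12, 25.13))
  edges <- data.frame(from = c("o", "c", "c"), to = c("c", "a", "b"),
                      length_km = c(2, 3, 4))
  river_network(nodes, edges)
}

# random valid count table
rand_table <- function(seed, n_samples = 8, n_otus = 40, depth = 500) {
  withr::with_seed(seed, {
    pr <- rlnorm(n_otus, 0, 1.5)
    cm <- t(vapply(seq_len(n_samples),
                   function(i) as.integer(rmultinom(1, depth, pr)),
                   integer(n_otus)))
    dimnames(cm) <- list(paste0("s", seq_len(n_samples)),
                         paste0("otu", seq_len(n_otus)))
    otu_table(cm)
  })
}

# ncm_input built directly from vectors (bypassing a table)
make_ncm_input <- function(p, freq, N, n_sites) {
  ni <- data.frame(otu_id = paste0("o", seq_along(p)), p = p, freq = freq)
  attr(ni, "N") <- N
  attr(ni, "n_sites") <- n_sites
  class(ni) <- c("ncm_input", "data.frame")
  ni
}
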