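# Independent oracles used across the suite.

# Brute-force diversity: enumerate every amino-acid sequence a small slot
# list can encode and count the distinct ones (feasible for <= 4 randomized
# slots).
enumerate_diversity <- function(slots, mixes = NULL) {
  if (length(slots) == 0) return(1) # empty product
  if (is.null(mixes)) {
    mixes <- lapply(stats::setNames(nm = c("mix1", "mix2", "mix3")),
                    mix_definition)
  }
  choices <- lapply(slots, function(s) {
    if (s$kind == "fixed") return("X")
    f <- mixes[[s$mix]]$frequencies
    names(f)[f > 0]
  })
  grid <- do.call(expand.grid, c(choices, stringsAsFactors = FALSE))
  length(unique(do.call(paste0, grid)))
}

# toy slot lists built directly (not via primers)
toy_slots <- function(mix_names) {
  lapply(mix_names, function(m) {
    if (grepl("^mix", m)) list(kind = "randomized", mix = m)
    else list(kind = "fixed", codon = m, partial = FALSE)
  })
}

# Exact E[# distinct] among n uniform draws from D types, via Stirling
# numbers of the second kind: P(K = k) = S(n,k) * D!/(D-k)! / D^n.
exact_expected_unique <- function(n, D) {
  if (n == 0) return(0)
  S <- matrix(0, n + 1, n + 1) # S[n+1, k+1] = S(n, k)
  S[1, 1] <- 1
  for (i in seq_len(n)) {
    for (k in seq_len(i)) {
      S[i + 1, k + 1] <- k * S[i, k + 1] + S[i, k]
    }
  }
  ks <- seq_len(min(n, D))
  falling <- vapply(ks, function(k) prod(D - seq_len(k) + 1), numeric(1))
  probs <- S[n + 1, ks + 1] * falling / D^n
  sum(ks * probs)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# reference values from the published kinetic characterization table
table5_rates <- data.frame(
  sybody = c("Sb_ENT1#1", "Sb_GlyT1#1", "Sb_GlyT1#2", "Sb_GlyT1#5"),
  kon = c(1.86e5, 1.88e5, 3.68e4, 4.54e5),
  koff = c(7.44e-3, 5.77e-2, 9.28e-2, 3.72e-2),
  KD = c(4.00e-8, 3.07e-7, 2.52e-6, 8.19e-8)
)
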