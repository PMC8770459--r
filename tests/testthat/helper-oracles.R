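# Independent oracles, kept deliberately separate from the package's code
# paths: closed-form receptor-noise contrasts for 2-4 receptor classes
# (standard di-/tri-/tetrachromat formulas coded term by term), and a naive
# trapezoid integrator.

oracle_dichromat <- function(df, e) {
  sqrt((df[1] - df[2])^2 / (e[1]^2 + e[2]^2))
}

oracle_trichromat <- function(df, e) {
  num <- e[1]^2 * (df[3] - df[2])^2 +
         e[2]^2 * (df[3] - df[1])^2 +
         e[3]^2 * (df[2] - df[1])^2
  den <- (e[1] * e[2])^2 + (e[1] * e[3])^2 + (e[2] * e[3])^2
  sqrt(num / den)
}

oracle_tetrachromat <- function(df, e) {
  num <- (e[1] * e[2])^2 * (df[4] - df[3])^2 +
         (e[1] * e[3])^2 * (df[4] - df[2])^2 +
         (e[1] * e[4])^2 * (df[3] - df[2])^2 +
         (e[2] * e[3])^2 * (df[4] - df[1])^2 +
         (e[2] * e[4])^2 * (df[3] - df[1])^2 +
         (e[3] * e[4])^2 * (df[2] - df[1])^2
  den <- (e[1] * e[2] * e[3])^2 + (e[1] * e[2] * e[4])^2 +
         (e[1] * e[3] * e[4])^2 + (e[2] * e[3] * e[4])^2
  sqrt(num / den)
}

oracle_closed_form <- function(df, e) {
  switch(length(df) - 1L,
         oracle_dichromat(df, e),
         oracle_trichromat(df, e),
         oracle_tetrachromat(df, e))
}

# Naive loop trapezoid, independent of the package's quadrature helper.
naive_trapz <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1L))
    s <- s + (x[i + 1L] - x[i]) * (y[i] + y[i + 1L]) / 2
  s
}

# Small deterministic dataset for pipeline tests.
tiny_dataset <- function(seed = 7, nb = 4, nf = 4, nl = 4) {
  genDataset(DatasetSpec(nBeetles = nb, nFlowers = nf, nLeaves = nl,
                         seed = seed))
}
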