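# Shared fixtures and independent oracles used across test files.

# Hand-computed index expectations: every value worked out on paper from
# the definitions (DBE = 1 + C - H/2 + N/2 + P/2; DBE_AI = 1 + C - O/2 -
# S - (N + P + H)/2; AI_mod = DBE_AI / (C - O/2 - N - S - P) clamped;
# NOSC = 4 - (4C + H - 3N - 2O + 5P - 2S)/C), then frozen.
hand_index_table <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
C  H  N  O  S  P  dbe  dbe_ai  ai_mod    nosc       cat                 oxy
6  6  0  0  0  0  4    4       0.666667  -1         aromatic            O_poor
6  12 0  6  0  0  1    -2      0         0          unsaturated         O_rich
1  4  0  0  0  0  0    0       0         -4         saturated           O_poor
16 34 0  0  0  0  0    0       0         -2.125     saturated           O_poor
14 6  0  2  0  0  12   11      0.846154  -0.142857  aromatic            O_poor
2  4  0  2  0  0  1    0       0         0          unsaturated         O_rich
8  8  0  4  0  0  5    3       0.5       0          highly_unsaturated  O_rich
27 34 2  9  0  0  12   5.5     0.268293  -0.370370  highly_unsaturated  O_poor
15 24 0  2  1  0  4    2       0.153846  -1.2       unsaturated         O_poor
20 20 0  0  0  0  11   11      0.55      -1         aromatic            O_poor
5  10 0  5  0  0  1    -1.5    0         0          unsaturated         O_rich
10 6  1  4  0  1  9    5       0.833333  0          aromatic            O_poor
30 62 2  3  0  0  1    -2.5    0         -1.666667  unsaturated         O_poor
9  9  1  3  0  0  6    3.5     0.538462  0          aromatic            O_poor
4  8  0  4  0  0  1    -1      0         0          unsaturated         O_rich
12 8  0  2  1  0  9    7       0.7       -0.166667  aromatic            O_poor
6  13 1  2  0  0  1    -1      0         -1         unsaturated         O_poor
18 15 0  13 0  1  12   4.5     0.428571  0.333333   highly_unsaturated  O_rich
2  2  0  4  0  0  2    0       0         3          highly_unsaturated  O_rich
1  2  0  1  0  0  1    0.5     1         0          aromatic            O_rich
16 18 0  9  2  0  8    1.5     0.157895  0.25       highly_unsaturated  O_rich
")
}

# Naive O(n^2) Rao quadratic entropy, the double-sum oracle.
naive_rao <- function(p, x) {
  s <- 0
  for (i in seq_along(p)) {
    for (j in seq_along(p)) {
      s <- s + p[i] * p[j] * abs(x[i] - x[j])
    }
  }
  s
}

# Six-nested-loop enumeration oracle for small element ranges.
naive_enumerate <- function(mass, cfg) {
  r <- cfg$ranges
  masses <- c(C = 12, H = 1.00782503, N = 14.00307401, O = 15.99491462,
    S = 31.97207117, P = 30.97376200)
  out <- list()
  for (C in r$C[1]:r$C[2]) {
    for (H in r$H[1]:r$H[2]) {
      for (N in r$N[1]:r$N[2]) {
        for (O in r$O[1]:r$O[2]) {
          for (S in r$S[1]:r$S[2]) {
            for (P in r$P[1]:r$P[2]) {
              m <- C * masses["C"] + H * masses["H"] + N * masses["N"] +
                O * masses["O"] + S * masses["S"] + P * masses["P"]
              if (abs(m - mass) / mass * 1e6 <= cfg$tol_ppm) {
                out[[length(out) + 1]] <- data.frame(
                  C = C, H = H, N = N, O = O, S = S, P = P
                )
              }
            }
          }
        }
      }
    }
  }
  if (!length(out)) {
    return(NULL)
  }
  do.call(rbind, out)
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# Builds an assigned_sample directly from a formula table and intensities,
# bypassing mass spectrometry: used to unit-test the diversity layer.
make_assigned <- function(f, intensity, sample_id = "s") {
  a <- cbind(
    data.frame(
      mz = formula_mass(f) - 1.00727646,
      intensity = intensity,
      formula = formula_string(f)
    ),
    f[c("C", "H", "N", "O", "S", "P")],
    data.frame(error_ppm = 0)
  )
  structure(
    list(
      sample_id = sample_id, assignments = a,
      unassigned = data.frame(mz = numeric(), intensity = numeric())
    ),
    class = "assigned_sample"
  )
}

# A small, fast survey configuration for unit tests of the generator and
# community layer (the acceptance suite runs the full default survey).
small_survey_config <- function(seed, n_lakes = 12, ...) {
  survey_config(
    n_lakes = n_lakes,
    pool_sizes = c(fresh = 250, highly_unsaturated = 350, aromatic = 200),
    seed = seed,
    ...
  )
}
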