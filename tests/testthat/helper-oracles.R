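# Independent oracles used across the suite.

# Exhaustive enumeration of all K^k directed neighbor paths from i: walks
# every choice sequence explicitly (revisits allowed) and totals the squared
# edge distances. Independent of the production recursion.
brute_diffusion_sum <- function(nm, D, i, k) {
  choices <- expand.grid(rep(list(seq_len(nm$K)), k))
  total <- 0
  for (r in seq_len(nrow(choices))) {
    node <- i
    s <- 0
    for (t in seq_len(k)) {
      nxt <- nm$nbr_idx[node, choices[r, t]]
      s <- s + D[node, nxt]^2
      node <- nxt
    }
    total <- total + s
  }
  total
}

# Double-loop Euclidean distance, independent of stats::dist
brute_distances <- function(X) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  D
}

# Brute-force local density: sorts the whole similarity row and sums the
# top-K entries (ties by ascending index via stable order)
brute_local_density <- function(Theta, K) {
  n <- nrow(Theta)
  vapply(seq_len(n), function(i) {
    v <- Theta[i, -i]
    sum(v[order(-v)][seq_len(min(K, n - 1L))])
  }, numeric(1))
}

# scikit-learn reference metrics, one python call for a whole batch of
# label pairs; returns a data.frame with columns ami, ari, fmi
sklearn_metrics <- function(pairs) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(
    lapply(pairs, function(p) list(t = p$t, p = p$p)), infile)
  code <- paste(
    "import json, sys",
    "from sklearn import metrics as M",
    "data = json.load(open(sys.argv[1]))",
    "out = [{'ami': M.adjusted_mutual_info_score(q['t'], q['p']),",
    "        'ari': M.adjusted_rand_score(q['t'], q['p']),",
    "        'fmi': M.fowlkes_mallows_score(q['t'], q['p'])}",
    "       for q in data]",
    "json.dump(out, open(sys.argv[2], 'w'))",
    sep = "\n")
  script <- tempfile(fileext = ".py")
  writeLines(code, script)
  status <- system2("python", c(script, infile, outfile),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("python/scikit-learn oracle failed")
  do.call(rbind, lapply(jsonlite::read_json(outfile), as.data.frame))
}

# small deterministic gaussian blobs for unit tests
tiny_blobs <- function(n_per = 30, gap = 10, seed = 7, d = 2) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * d, 0, 0.5), n_per, d),
             matrix(rnorm(n_per * d, gap, 0.5), n_per, d))
  pointset(X, y_true = rep(1:2, each = n_per))
}

rotation2 <- function(angle) {
  matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
}
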