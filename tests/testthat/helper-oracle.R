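# Independent brute-force Vietoris-Rips persistence (full boundary-matrix
# reduction in filtration order, no clearing, no shortcuts). Tiny inputs
# only; used to validate the fast reduction.
rips_oracle <- function(D, threshold, p = 47) {
  n <- nrow(D)
  simp <- list()
  for (d in 0:3) {
    combs <- utils::combn(n, d + 1)
    for (c_i in seq_len(ncol(combs))) {
      v <- combs[, c_i]
      f <- if (d == 0) 0 else max(D[v, v][upper.tri(D[v, v])])
      if (f <= threshold)
        simp[[length(simp) + 1]] <- list(v = v, f = f, d = d)
    }
  }
  f_all <- vapply(simp, `[[`, numeric(1), "f")
  d_all <- vapply(simp, `[[`, numeric(1), "d")
  lex <- vapply(simp, function(s) paste(sprintf("%04d", s$v), collapse = ""),
                character(1))
  ord <- order(f_all, d_all, lex)
  simp <- simp[ord]
  key <- vapply(simp, function(s) paste(s$v, collapse = "-"), character(1))
  pos <- stats::setNames(seq_along(simp), key)

  m <- length(simp)
  cols <- vector("list", m)   # named numeric: names = row index, values = coeff
  for (j in seq_len(m)) {
    s <- simp[[j]]
    if (s$d == 0) { cols[[j]] <- numeric(0); next }
    entries <- numeric(0)
    for (drop in seq_along(s$v)) {
      face <- s$v[-drop]
      r <- pos[[paste(face, collapse = "-")]]
      coef <- if (drop %% 2 == 1) 1 else p - 1
      entries[as.character(r)] <- coef
    }
    cols[[j]] <- entries
  }
  low <- function(col) if (length(col) == 0) 0L else max(as.integer(names(col)))
  pivot_owner <- integer(m)
  pairs <- matrix(0L, 0, 2)
  for (j in seq_len(m)) {
    col <- cols[[j]]
    repeat {
      l <- low(col)
      if (l == 0L || pivot_owner[l] == 0L) break
      other <- cols[[pivot_owner[l]]]
      mult <- (p - col[[as.character(l)]]) *
        as.integer(solve_mod(other[[as.character(l)]], p)) %% p
      for (r in names(other)) {
        col[r] <- ((if (is.na(col[r])) 0 else col[r]) + other[[r]] * mult) %% p
        if (col[r] == 0) col <- col[names(col) != r]
      }
    }
    cols[[j]] <- col
    l <- low(col)
    if (l > 0L) {
      pivot_owner[l] <- j
      pairs <- rbind(pairs, c(l, j))
    }
  }
  paired <- c(pairs[, 1], pairs[, 2])
  bars <- data.frame(dim = integer(0), birth = numeric(0),
                     death = numeric(0))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (simp[[j]]$f > simp[[i]]$f)
      bars <- rbind(bars, data.frame(dim = simp[[i]]$d, birth = simp[[i]]$f,
                                     death = simp[[j]]$f))
  }
  for (j in seq_len(m)) {
    if (!(j %in% paired) && length(cols[[j]]) == 0 && simp[[j]]$d <= 2)
      bars <- rbind(bars, data.frame(dim = simp[[j]]$d, birth = simp[[j]]$f,
                                     death = Inf))
  }
  bars[order(bars$dim, bars$birth, bars$death), ]
}

solve_mod <- function(a, p) {
  # modular inverse by Fermat (p prime, small)
  r <- 1L
  a <- as.integer(a %% p)
  e <- p - 2L
  while (e > 0L) {
    if (e %% 2L == 1L) r <- (r * a) %% p
    a <- (a * a) %% p
    e <- e %/% 2L
  }
  r
}

# sorted (dim, birth, death) with finite rounding, for multiset comparison
bar_table <- function(df, digits = 5) {
  df <- df[order(df$dim, round(df$birth, digits), round(df$death, digits)), ]
  data.frame(dim = df$dim, birth = round(df$birth, digits),
             death = round(df$death, digits))
}
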