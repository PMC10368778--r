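# Independent oracles, deliberately naive: used to freeze expected
# values, never shared with the implementation under test.

# edit distance straight from the recursive definition (memoised)
lev_recursive <- function(a, b, sub_cost = 1L) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res <- min(
      rec(i - 1L, j) + 1L,
      rec(i, j - 1L) + 1L,
      rec(i - 1L, j - 1L) +
        if (av[i] == bv[j]) 0L else sub_cost
    )
    memo[[key]] <- res
    res
  }
  rec(length(av), length(bv))
}

# all strings of length 0..max_len over an alphabet
all_strings <- function(alphabet, max_len) {
  out <- ""
  acc <- list("")
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), len),
                      stringsAsFactors = FALSE))
    acc[[len + 1L]] <- do.call(paste0, grid)
  }
  unlist(acc)
}

# two-way within-subject sums-of-squares decomposition, written out
# longhand (independent of stats::aov)
rm_anova_twoway_oracle <- function(d) {
  # d: columns id, A, B, y; complete balanced
  n <- length(unique(d$id))
  a <- length(unique(d$A))
  b <- length(unique(d$B))
  grand <- mean(d$y)
  mA <- tapply(d$y, d$A, mean)
  mB <- tapply(d$y, d$B, mean)
  mAB <- tapply(d$y, list(d$A, d$B), mean)
  mS <- tapply(d$y, d$id, mean)
  mSA <- tapply(d$y, list(d$id, d$A), mean)
  mSB <- tapply(d$y, list(d$id, d$B), mean)
  ss_A <- n * b * sum((mA - grand)^2)
  ss_B <- n * a * sum((mB - grand)^2)
  ss_AB <- n * sum((sweep(sweep(mAB, 1, mA), 2, mB) + grand)^2)
  ss_SA <- b * sum((mSA - outer(mS, rep(1, a)) -
                      outer(rep(1, n), mA) + grand)^2)
  ss_SB <- a * sum((mSB - outer(mS, rep(1, b)) -
                      outer(rep(1, n), mB) + grand)^2)
  # residual: y - cell - subject-margin effects
  ss_tot <- sum((d$y - grand)^2)
  ss_S <- a * b * sum((mS - grand)^2)
  ss_SAB <- ss_tot - ss_S - ss_A - ss_B - ss_AB - ss_SA - ss_SB
  f <- function(ss_eff, df_eff, ss_err, df_err) {
    F <- (ss_eff / df_eff) / (ss_err / df_err)
    list(df1 = df_eff, df2 = df_err, F = F,
         p = pf(F, df_eff, df_err, lower.tail = FALSE))
  }
  list(
    A = f(ss_A, a - 1, ss_SA, (n - 1) * (a - 1)),
    B = f(ss_B, b - 1, ss_SB, (n - 1) * (b - 1)),
    AB = f(ss_AB, (a - 1) * (b - 1), ss_SAB,
           (n - 1) * (a - 1) * (b - 1))
  )
}
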