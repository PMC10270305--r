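# Vectorised category-5 feature extraction on the shared day grid.
#
# Works on the same Y (observed), W (observed mask) and P (expected) matrices
# as the batched quantile fit: runs of negative residuals are identified over
# the flattened cow x day matrix with one cumsum, and all per-run and
# per-cow aggregates are computed with rowsum/tabulate/order tricks — no
# per-cow R loop. Semantics match detect_perturbations_core()/pert_core()
# exactly (a test asserts the two routes agree).
pert_features_grid <- function(Y, W, P, min_len = 5, major_threshold = 0.85,
                               tol = 1e-3) {
  ngrid <- nrow(Y)
  n <- ncol(Y)
  zero <- rep(0, n)
  out <- list(PertNoTotal = zero, PertNoMinor = zero, PertNoMajor = zero,
              PertMinDaysDev = zero, PertMinDaysRec = zero,
              PertMajDaysDev = zero, PertMajDaysRec = zero,
              PertMinMilkLoss = zero, PertMajMilkLoss = zero,
              PertTotalLoss = zero, PertDeepest = zero)

  neg <- W == 1 & (Y - P) < -tol
  flat <- as.logical(neg)
  N <- length(flat)
  if (!any(flat)) return(out)
  colv <- rep.int(seq_len(n), rep.int(ngrid, n))
  chg <- flat[-1] != flat[-N] | colv[-1] != colv[-N]
  rid <- cumsum(c(TRUE, chg))
  pos <- which(flat)
  r0 <- rid[pos]
  len0 <- tabulate(r0)
  keep <- len0[r0] >= min_len
  pos <- pos[keep]
  if (length(pos) == 0) return(out)
  rf <- match(r0[keep], unique(r0[keep]))   # dense run ids, in order
  day <- (pos - 1L) %% ngrid + 1L
  cow <- colv[pos]
  def <- P[pos] - Y[pos]
  rat <- ifelse(P[pos] > 0, Y[pos] / P[pos], 1)
  below <- rat < major_threshold

  first <- !duplicated(rf)
  last <- !duplicated(rf, fromLast = TRUE)
  start_day <- day[first]
  end_day <- day[last]
  cow_run <- cow[first]
  n_runs <- sum(first)

  # earliest day of maximum deficit per run (stable order keeps day order)
  o <- order(rf, -def)
  sel <- !duplicated(rf[o])
  deep_day <- day[o][sel]
  deep_def <- def[o][sel]

  # qualification and severity: longest stretch of successive deep days
  qualify <- rowsum(as.numeric(below), rf) > 0
  deep_run_len <- rep(0, n_runs)
  if (any(below)) {
    bchg <- below[-1] != below[-length(below)] |
      rf[-1] != rf[-length(rf)] | day[-1] != day[-length(day)] + 1L
    bid <- cumsum(c(TRUE, bchg))
    bpos <- which(below)
    blen <- tabulate(bid[bpos])
    bfirst <- bpos[!duplicated(bid[bpos])]
    parent <- rf[bfirst]
    this_len <- blen[bid[bfirst]]
    o2 <- order(parent, -this_len)
    sel2 <- !duplicated(parent[o2])
    deep_run_len[parent[o2][sel2]] <- this_len[o2][sel2]
  }

  loss <- as.numeric(rowsum(def, rf))
  dev_days <- deep_day - start_day + 1L
  rec_days <- end_day - deep_day

  q <- as.logical(qualify)
  if (!any(q)) return(out)
  major <- deep_run_len >= min_len
  cw <- cow_run[q]
  mj <- major[q]
  dv <- dev_days[q]; rc <- rec_days[q]; ls <- loss[q]; dd <- deep_def[q]

  add_by_cow <- function(x, subset) {
    v <- rep(0, n)
    if (any(subset)) {
      s <- rowsum(x[subset], cw[subset])
      v[as.integer(rownames(s))] <- s
    }
    v
  }
  n_minor <- add_by_cow(rep(1, length(cw)), !mj)
  n_major <- add_by_cow(rep(1, length(cw)), mj)
  out$PertNoMinor <- n_minor
  out$PertNoMajor <- n_major
  out$PertNoTotal <- n_minor + n_major
  out$PertMinDaysDev <- ifelse(n_minor > 0, add_by_cow(dv, !mj) / n_minor, 0)
  out$PertMinDaysRec <- ifelse(n_minor > 0, add_by_cow(rc, !mj) / n_minor, 0)
  out$PertMajDaysDev <- ifelse(n_major > 0, add_by_cow(dv, mj) / n_major, 0)
  out$PertMajDaysRec <- ifelse(n_major > 0, add_by_cow(rc, mj) / n_major, 0)
  out$PertMinMilkLoss <- add_by_cow(ls, !mj)
  out$PertMajMilkLoss <- add_by_cow(ls, mj)
  out$PertTotalLoss <- out$PertMinMilkLoss + out$PertMajMilkLoss
  o3 <- order(cw, -ls)
  sel3 <- !duplicated(cw[o3])
  deepest <- rep(0, n)
  deepest[cw[o3][sel3]] <- dd[o3][sel3]
  out$PertDeepest <- deepest
  out
}
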