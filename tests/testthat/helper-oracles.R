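# Independent oracles, implemented by different algorithms than the package
# code they check.

# Exact continuous-time event-driven replication oracle for deterministic
# single-chromosome programs (all origins licensed, no termination, no
# modifier). Returns the merged replicated segments at tExp.
eventOracleSegments <- function(x, t0, vL, vR, len, tExp) {
  eps <- 1e-9
  ord <- order(x)
  x <- x[ord]; t0 <- t0[ord]; vL <- vL[ord]; vR <- vR[ord]
  n <- length(x)
  fired <- rep(FALSE, n)
  passive <- rep(FALSE, n)
  # bubbles: list of list(l, r, vl, vr, la, ra) ordered by position
  bubs <- list()
  tcur <- 0

  advance <- function(bubs, dtm) {
    for (k in seq_along(bubs)) {
      if (bubs[[k]]$la) bubs[[k]]$l <- bubs[[k]]$l - bubs[[k]]$vl * dtm
      if (bubs[[k]]$ra) bubs[[k]]$r <- bubs[[k]]$r + bubs[[k]]$vr * dtm
    }
    bubs
  }
  covered <- function(bubs, pos) {
    for (b in bubs) if (pos >= b$l - eps && pos <= b$r + eps) return(TRUE)
    FALSE
  }

  repeat {
    cand <- tExp
    # next firing
    unf <- which(!fired & !passive & t0 <= tExp)
    if (length(unf)) cand <- min(cand, min(t0[unf]))
    # collisions between adjacent bubbles
    if (length(bubs) > 1) for (k in seq_len(length(bubs) - 1)) {
      gap <- bubs[[k + 1]]$l - bubs[[k]]$r
      vsum <- (if (bubs[[k]]$ra) bubs[[k]]$vr else 0) +
        (if (bubs[[k + 1]]$la) bubs[[k + 1]]$vl else 0)
      if (vsum > 0 && gap >= -eps) cand <- min(cand, tcur + max(gap, 0) / vsum)
    }
    # chromosome-end reaches
    for (b in bubs) {
      if (b$la) cand <- min(cand, tcur + b$l / b$vl)
      if (b$ra) cand <- min(cand, tcur + (len - b$r) / b$vr)
    }
    cand <- max(cand, tcur)
    bubs <- advance(bubs, cand - tcur)
    tcur <- cand
    if (tcur >= tExp - eps) break

    # process all events due now
    # (1) end reaches
    for (k in seq_along(bubs)) {
      if (bubs[[k]]$la && bubs[[k]]$l <= eps) {
        bubs[[k]]$l <- 0; bubs[[k]]$la <- FALSE
      }
      if (bubs[[k]]$ra && bubs[[k]]$r >= len - eps) {
        bubs[[k]]$r <- len; bubs[[k]]$ra <- FALSE
      }
    }
    # (2) collisions (leftmost first)
    k <- 1
    while (k < length(bubs)) {
      if (bubs[[k + 1]]$l - bubs[[k]]$r <= eps) {
        mid <- (bubs[[k]]$r + bubs[[k + 1]]$l) / 2
        merged <- list(l = bubs[[k]]$l, r = bubs[[k + 1]]$r,
                       vl = bubs[[k]]$vl, vr = bubs[[k + 1]]$vr,
                       la = bubs[[k]]$la, ra = bubs[[k + 1]]$ra)
        bubs[[k]] <- merged
        bubs[[k + 1]] <- NULL
      } else k <- k + 1
    }
    # (3) firings due at tcur
    due <- which(!fired & !passive & t0 <= tcur + eps)
    for (i in due) {
      if (covered(bubs, x[i])) { passive[i] <- TRUE; next }
      fired[i] <- TRUE
      nb <- list(l = x[i], r = x[i], vl = vL[i], vr = vR[i],
                 la = TRUE, ra = TRUE)
      pos <- vapply(bubs, function(b) b$l, numeric(1))
      at <- sum(pos < x[i])
      bubs <- append(bubs, list(nb), after = at)
    }
    if (length(bubs) == 1 && !bubs[[1]]$la && !bubs[[1]]$ra) break
    if (length(bubs) == 0 && !length(which(!fired & !passive & t0 <= tExp)))
      break
  }
  if (length(bubs) == 0)
    return(data.frame(start = numeric(0), end = numeric(0)))
  data.frame(start = pmax(0, vapply(bubs, function(b) b$l, numeric(1))),
             end = pmin(len, vapply(bubs, function(b) b$r, numeric(1))))
}

# brute-force union of closed intervals; returns merged lengths sorted
mergedLengths <- function(starts, ends, tol = 1e-6) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out <- numeric(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me + tol) me <- max(me, ends[i])
    else { out <- c(out, me - ms); ms <- starts[i]; me <- ends[i] }
  }
  sort(c(out, me - ms))
}

# naive double-loop RSS over the union of occupied bins
naiveRss <- function(h1, h2) {
  k1 <- round(binStarts(h1) / binWidth(h1))
  k2 <- round(binStarts(h2) / binWidth(h2))
  total <- 0
  for (k in union(k1, k2)) {
    f1 <- if (k %in% k1) frequencies(h1)[which(k1 == k)] else 0
    f2 <- if (k %in% k2) frequencies(h2)[which(k2 == k)] else 0
    total <- total + (f1 - f2)^2
  }
  total
}

# KS distance by evaluating both ECDFs at every pooled point
naiveKs <- function(a, b) {
  pts <- c(a, b)
  max(vapply(pts, function(p) abs(mean(a <= p) - mean(b <= p)), numeric(1)))
}
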