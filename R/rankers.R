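# The six learning-to-rank algorithms and the SVR baseline, under one
# query-grouped fit/score contract. Pair-wise constructions are strictly
# within-query: ordered pairs never span two targets, which is what makes
# training labels measured on different platforms mutually compatible.

#' Construct a RankingGroup
#'
#' @param targetId character scalar.
#' @param features numeric matrix, one row per compound.
#' @param grades integer relevance grades (0-4), one per row.
#' @param compoundIds character ids; defaults to row numbers.
#' @return a \linkS4class{RankingGroup}.
#' @export
RankingGroup <- function(targetId, features, grades,
                         compoundIds = as.character(seq_len(nrow(features)))) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  new("RankingGroup", targetId = as.character(targetId), features = features,
      grades = as.integer(grades), compoundIds = as.character(compoundIds))
}

#' Enumerate within-query ordered preference pairs
#'
#' Returns every ordered pair (i, j) of items in one group whose first
#' member has a strictly higher grade than the second — the instance unit
#' of pair-wise ranking. Pairs are emitted in deterministic order
#' (i ascending, then j ascending) and never cross queries.
#'
#' @param x a \linkS4class{RankingGroup}, or an integer/numeric grade vector.
#' @return a two-column integer matrix with columns \code{preferred} and
#'   \code{other}; zero rows when no strict preference exists.
#' @export
enumeratePairs <- function(x) {
  g <- if (is(x, "RankingGroup")) x@grades else x
  n <- length(g)
  out <- matrix(integer(0), ncol = 2L,
                dimnames = list(NULL, c("preferred", "other")))
  if (n < 2L) return(out)
  idx <- which(outer(g, g, ">"), arr.ind = TRUE)        # row i > col j
  if (!nrow(idx)) return(out)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  dimnames(idx) <- list(NULL, c("preferred", "other"))
  idx
}

# Pool a group list into one matrix with bookkeeping.
.poolGroups <- function(groups) {
  stopifnot(length(groups) > 0L)
  X <- do.call(rbind, lapply(groups, function(g) g@features))
  list(X = X,
       grades = unlist(lapply(groups, function(g) g@grades)),
       query = rep(seq_along(groups),
                   vapply(groups, function(g) length(g@grades), integer(1))),
       ids = unlist(lapply(groups, function(g) g@compoundIds)))
}

# Global-index ordered pairs across groups (still within-query).
.globalPairs <- function(groups) {
  off <- cumsum(c(0L, vapply(groups, function(g) length(g@grades),
                             integer(1))))
  ps <- lapply(seq_along(groups), function(q) {
    p <- enumeratePairs(groups[[q]])
    if (nrow(p)) p + off[q] else p
  })
  do.call(rbind, ps)
}

.newModel <- function(algorithm, params, hyper, seed, dim) {
  new("RankerModel", algorithm = algorithm, params = params, hyper = hyper,
      seed = as.integer(seed), dim = as.integer(dim), fitted = TRUE)
}

.checkDim <- function(model, X) {
  if (ncol(X) != model@dim)
    stop(sprintf("feature dimension %d does not match the fitted model (%d)",
                 ncol(X), model@dim))
}

#' @describeIn scoreFeatures score a feature matrix with any fitted ranker.
setMethod("scoreFeatures", "RankerModel", function(model, X) {
  if (!model@fitted) stop("model is not fitted")
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  .checkDim(model, X)
  p <- model@params
  switch(model@algorithm,
    prank    = ,
    svmrank  = ,
    listnet  = drop(X %*% p$w),
    ranknet  = {
      if (length(p$W1)) {
        H <- 1 / (1 + exp(-(X %*% p$W1 + matrix(p$b1, nrow(X),
                                                length(p$b1), byrow = TRUE))))
        drop(H %*% p$w2) + p$b2
      } else drop(X %*% p$w)
    },
    rankboost = {
      s <- numeric(nrow(X))
      for (t in seq_along(p$alpha))
        s <- s + p$alpha[t] * (X[, p$feature[t]] > p$threshold[t])
      s
    },
    adarank  = drop(X[, p$feature, drop = FALSE] %*% p$alpha),
    svr_baseline = .svrScore(p, X),
    stop("unknown algorithm")
  )
})

#' Score each group with a fitted ranker
#'
#' @param model a fitted \linkS4class{RankerModel}.
#' @param groups list of \linkS4class{RankingGroup}.
#' @return named list of numeric score vectors, one per group.
#' @export
scoreGroups <- function(model, groups) {
  out <- lapply(groups, function(g) scoreFeatures(model, g@features))
  names(out) <- vapply(groups, function(g) g@targetId, character(1))
  out
}

#' Fit a ranker by algorithm name
#'
#' Uniform dispatcher over the six learning-to-rank algorithms and the SVR
#' baseline, used by the experiment strategies.
#'
#' @param algorithm one of \code{"prank"}, \code{"ranknet"},
#'   \code{"rankboost"}, \code{"svmrank"}, \code{"adarank"},
#'   \code{"listnet"}, \code{"svr_baseline"}.
#' @param groups list of \linkS4class{RankingGroup} (training queries).
#' @param hyper named list of hyperparameter overrides for the specific
#'   fitter.
#' @param seed integer RNG seed.
#' @return a fitted \linkS4class{RankerModel}.
#' @export
fitRanker <- function(algorithm, groups, hyper = list(), seed = 1L) {
  algorithm <- match.arg(algorithm, .ALGORITHMS)
  call1 <- function(f) do.call(f, c(list(groups = groups, seed = seed), hyper))
  switch(algorithm,
    prank        = call1(fitPRank),
    ranknet      = call1(fitRankNet),
    rankboost    = call1(fitRankBoost),
    svmrank      = call1(fitSVMRank),
    adarank      = do.call(fitAdaRank, c(list(groups = groups), hyper)),
    listnet      = call1(fitListNet),
    svr_baseline = do.call(fitSVRBaseline, c(list(groups = groups), hyper)))
}

# ---- point-wise: PRank -----------------------------------------------------

#' PRank: online ordinal-regression perceptron
#'
#' Point-wise ranker. Maintains a weight vector w (initialized 0) and
#' non-decreasing thresholds b_1 <= ... <= b_{K-1} (initialized 0, with
#' b_K = +Inf) cutting the score axis into K ordered ranks; the predicted
#' rank of x is the smallest r with \code{w.x - b_r < 0}. For a training
#' example with true rank y, every threshold on the wrong side of the score
#' triggers a correction: tau_r = y_r when \code{(w.x - b_r) * y_r <= 0}
#' (else 0) with y_r = +1 for y > r and -1 otherwise, then
#' \code{w <- w + sum(tau) * x} and \code{b_r <- b_r - tau_r}. The update
#' provably keeps the thresholds sorted. Instances are pooled over queries
#' and shuffled each epoch with the given seed.
#'
#' @param groups list of \linkS4class{RankingGroup}; grades 0..K-1, K >= 2.
#' @param epochs training passes (default 50).
#' @param seed RNG seed for the per-epoch shuffles.
#' @param trace record the threshold vector after every update in
#'   \code{params$bTrace} (diagnostic; default FALSE).
#' @return fitted \linkS4class{RankerModel} with params \code{w} and
#'   \code{b}; ranking scores are \code{w.x}.
#' @export
fitPRank <- function(groups, epochs = 50L, seed = 1L, trace = FALSE) {
  pool <- .poolGroups(groups)
  y <- pool$grades + 1L                        # ranks 1..K
  K <- max(y)
  if (K < 2L || length(unique(y)) < 2L)
    stop("PRank needs at least 2 distinct ranks")
  d <- ncol(pool$X)
  w <- numeric(d)
  b <- numeric(K - 1L)
  n <- nrow(pool$X)
  bTrace <- list()
  set.seed(seed)
  for (ep in seq_len(epochs)) {
    for (i in sample.int(n)) {
      upd <- prankSingleUpdate(w, b, pool$X[i, ], y[i])
      if (upd$changed) {
        w <- upd$w; b <- upd$b
        if (trace) bTrace[[length(bTrace) + 1L]] <- b
      }
    }
  }
  params <- list(w = w, b = b, K = K)
  if (trace) params$bTrace <- bTrace
  .newModel("prank", params, list(epochs = epochs), seed, d)
}

#' One PRank perceptron update
#'
#' Applies the PRank correction rule to a single training example and
#' returns the updated weight vector and thresholds (see [fitPRank()] for
#' the rule). Exposed so the update is auditable in isolation.
#'
#' @param w current weight vector.
#' @param b current threshold vector (length K-1).
#' @param x feature vector of the example.
#' @param rank true rank of the example, 1-based (grade + 1).
#' @return list with \code{w}, \code{b}, and \code{changed} (whether any
#'   correction fired).
#' @export
prankSingleUpdate <- function(w, b, x, rank) {
  K <- length(b) + 1L
  s <- sum(w * x)
  yr <- ifelse(rank > seq_len(K - 1L), 1, -1)
  tau <- ifelse((s - b) * yr <= 0, yr, 0)
  if (any(tau != 0)) list(w = w + sum(tau) * x, b = b - tau, changed = TRUE)
  else list(w = w, b = b, changed = FALSE)
}

#' Predict the ordinal rank under a PRank model
#'
#' @param model a fitted PRank \linkS4class{RankerModel}.
#' @param X feature matrix or single vector.
#' @return integer predicted ranks on the grade scale 0..K-1.
#' @export
predictRank <- function(model, X) {
  stopifnot(model@algorithm == "prank", model@fitted)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  s <- drop(as.matrix(X) %*% model@params$w)
  b <- c(model@params$b, Inf)
  vapply(s, function(si) which(si - b < 0)[1L], integer(1)) - 1L
}

# ---- pair-wise: RankNet ----------------------------------------------------

#' RankNet: pair-wise cross-entropy ranker
#'
#' For every within-query ordered pair (i preferred over j) the modeled
#' preference probability is \code{P_ij = sigmoid(f(x_i) - f(x_j))} with
#' target probability 1, and the loss is the summed binary cross-entropy
#' \code{-log P_ij}. The scorer f is linear by default
#' (\code{hiddenUnits = 0}) or a one-hidden-layer network with sigmoid
#' activations. Training is full-batch gradient descent with seeded
#' initialization and step halving, so the training loss is non-increasing.
#'
#' @param groups list of \linkS4class{RankingGroup}.
#' @param hiddenUnits 0 for a linear scorer (default), or the hidden-layer
#'   width.
#' @param learningRate initial gradient-descent step (default 0.01).
#' @param epochs gradient steps (default 200).
#' @param seed RNG seed for weight initialization.
#' @return fitted \linkS4class{RankerModel}; params carry \code{w} (linear)
#'   or \code{W1, b1, w2, b2}, plus the training \code{loss} trace.
#' @export
fitRankNet <- function(groups, hiddenUnits = 0L, learningRate = 0.01,
                       epochs = 200L, seed = 1L) {
  pool <- .poolGroups(groups)
  pr <- .globalPairs(groups)
  if (!nrow(pr)) stop("no ordered pairs in the training data")
  X <- pool$X; d <- ncol(X)
  set.seed(seed)
  if (hiddenUnits > 0L) {
    par <- list(W1 = matrix(stats::rnorm(d * hiddenUnits, sd = 0.1), d),
                b1 = numeric(hiddenUnits),
                w2 = stats::rnorm(hiddenUnits, sd = 0.1), b2 = 0)
  } else {
    par <- list(w = stats::rnorm(d, sd = 0.01))
  }
  fwd <- function(par) {
    if (hiddenUnits > 0L) {
      H <- 1 / (1 + exp(-(X %*% par$W1 +
                          matrix(par$b1, nrow(X), hiddenUnits, byrow = TRUE))))
      list(f = drop(H %*% par$w2) + par$b2, H = H)
    } else list(f = drop(X %*% par$w))
  }
  lossOf <- function(f) {
    dlt <- f[pr[, 1L]] - f[pr[, 2L]]
    sum(log1p(exp(-dlt)))
  }
  grad <- function(par, fw) {
    dlt <- fw$f[pr[, 1L]] - fw$f[pr[, 2L]]
    gpair <- -1 / (1 + exp(dlt))               # dL/d(f_i - f_j)
    gf <- numeric(nrow(X))                      # dL/df per instance
    gf <- gf + as.vector(tapply(c(gpair, -gpair),
                                c(pr[, 1L], pr[, 2L]), sum)[
                           as.character(seq_len(nrow(X)))])
    gf[is.na(gf)] <- 0
    if (hiddenUnits > 0L) {
      dh <- (gf * fw$H * (1 - fw$H)) * rep(par$w2, each = nrow(X))
      dim(dh) <- dim(fw$H)
      list(W1 = crossprod(X, dh), b1 = colSums(dh),
           w2 = drop(crossprod(fw$H, gf)), b2 = sum(gf))
    } else list(w = drop(crossprod(X, gf)))
  }
  fw <- fwd(par); cur <- lossOf(fw$f)
  trace <- numeric(epochs)
  lr <- learningRate
  for (ep in seq_len(epochs)) {
    g <- grad(par, fw)
    repeat {
      cand <- Map(function(p, gi) p - lr * gi, par, g)
      fw2 <- fwd(cand); new <- lossOf(fw2$f)
      if (new <= cur || lr < 1e-12) break
      lr <- lr / 2
    }
    if (new <= cur) { par <- cand; fw <- fw2; cur <- new }
    trace[ep] <- cur
  }
  .newModel("ranknet", c(par, list(loss = trace)),
            list(hiddenUnits = hiddenUnits, learningRate = learningRate,
                 epochs = epochs), seed, d)
}

# ---- pair-wise: RankBoost --------------------------------------------------

#' RankBoost: boosting over ordered pairs
#'
#' Maintains a distribution D over the within-query ordered pairs
#' (initialized uniform). Weak rankers are single-feature threshold
#' functions \code{h(x) = 1[x_f > theta]} with candidate thresholds at the
#' midpoints of each feature's sorted distinct values; each round picks the
#' weak ranker maximizing \code{r = sum_p D(p) (h(x_pref) - h(x_other))},
#' sets \code{alpha = 0.5 log((1 + r)/(1 - r))} (r clipped to
#' +/-(1 - 1e-10) so a perfect weak ranker cannot produce an infinite
#' weight), reweights \code{D <- D exp(-alpha (h_pref - h_other))} and
#' renormalizes. The final score is \code{sum_t alpha_t h_t(x)}. Boosting
#' stops early when no weak ranker achieves r > 0.
#'
#' @param groups list of \linkS4class{RankingGroup}.
#' @param rounds boosting rounds (default 100).
#' @param seed stored for reproducibility bookkeeping (the fit itself is
#'   deterministic).
#' @param trace record the pair distribution after every round in
#'   \code{params$DTrace} (diagnostic; default FALSE).
#' @return fitted \linkS4class{RankerModel}; params carry parallel vectors
#'   \code{feature}, \code{threshold}, \code{alpha}.
#' @export
fitRankBoost <- function(groups, rounds = 100L, seed = 1L, trace = FALSE) {
  pool <- .poolGroups(groups)
  pr <- .globalPairs(groups)
  if (!nrow(pr)) stop("no ordered pairs in the training data")
  X <- pool$X; n <- nrow(X); d <- ncol(X)
  P <- nrow(pr)
  D <- rep(1 / P, P)
  ordCache <- lapply(seq_len(d), function(f) order(X[, f], decreasing = TRUE))
  feat <- thr <- alp <- numeric(0)
  DTrace <- list()
  for (t in seq_len(rounds)) {
    # instance potentials: pi[i] = sum_p D(p) ([i preferred] - [i other])
    pot <- numeric(n)
    agg <- tapply(c(D, -D), c(pr[, 1L], pr[, 2L]), sum)
    pot[as.integer(names(agg))] <- agg
    best <- list(r = 0, f = NA, theta = NA)
    for (f in seq_len(d)) {
      o <- ordCache[[f]]
      v <- X[o, f]
      cs <- cumsum(pot[o])
      dup <- duplicated(v)                    # last index of each distinct run
      lastOfRun <- which(!dup[-1L])           # prefix ends between distinct vals
      if (!length(lastOfRun)) next            # constant feature
      rs <- cs[lastOfRun]
      bi <- which.max(rs)
      if (rs[bi] > best$r + 1e-15) {
        theta <- (v[lastOfRun[bi]] + v[lastOfRun[bi] + 1L]) / 2
        best <- list(r = rs[bi], f = f, theta = theta)
      }
    }
    if (is.na(best$f) || best$r <= 0) break
    r <- min(max(best$r, -(1 - 1e-10)), 1 - 1e-10)
    a <- 0.5 * log((1 + r) / (1 - r))
    h <- as.numeric(X[, best$f] > best$theta)
    D <- D * exp(-a * (h[pr[, 1L]] - h[pr[, 2L]]))
    D <- D / sum(D)
    if (trace) DTrace[[length(DTrace) + 1L]] <- D
    feat <- c(feat, best$f); thr <- c(thr, best$theta); alp <- c(alp, a)
  }
  if (!length(feat))
    stop("RankBoost found no weak ranker with positive weighted accuracy")
  params <- list(feature = as.integer(feat), threshold = thr, alpha = alp)
  if (trace) params$DTrace <- DTrace
  .newModel("rankboost", params, list(rounds = rounds), seed, d)
}

# ---- pair-wise: ranking SVM ------------------------------------------------

#' Ranking SVM (pair-difference reduction)
#'
#' Reduces ranking to classification of within-query pair differences
#' (Herbrich/Joachims): every ordered pair contributes the difference
#' vector \code{x_pref - x_other} with label +1, and a linear
#' maximum-margin classifier with L2 regularization and hinge loss is
#' fitted through the origin (no intercept; the mirrored negative pairs
#' would only flip signs). The primal problem
#' \deqn{\min_w \; \tfrac{1}{2}\|w\|^2 + C \sum_p \max(0, 1 - w.(x_i - x_j))}
#' is solved exactly in its dual by coordinate descent over the pair
#' multipliers (the liblinear scheme, specialized to no intercept), with a
#' seeded random sweep order. The learned direction is equivalent to the
#' specialized ranking-SVM solvers for linear kernels.
#'
#' @param groups list of \linkS4class{RankingGroup}.
#' @param C soft-margin cost per pair (default 1).
#' @param passes maximum coordinate-descent sweeps over the pairs
#'   (default 20; stops early once the largest multiplier change in a
#'   sweep falls below \code{tol}).
#' @param tol early-stopping tolerance (default 1e-4).
#' @param seed RNG seed for the sweep order.
#' @return fitted \linkS4class{RankerModel} with params \code{w}.
#' @export
fitSVMRank <- function(groups, C = 1, passes = 20L, tol = 1e-4, seed = 1L) {
  pool <- .poolGroups(groups)
  pr <- .globalPairs(groups)
  if (!nrow(pr)) stop("no ordered pairs in the training data")
  X <- pool$X; d <- ncol(X); P <- nrow(pr)
  ip <- pr[, 1L]; io <- pr[, 2L]
  set.seed(seed)
  order <- vapply(seq_len(passes), function(p) sample.int(P),
                  integer(P))
  dim(order) <- c(P, passes)
  sol <- .svmrankDualCD(X, as.integer(ip), as.integer(io), C, order, tol)
  .newModel("svmrank", list(w = sol$w), list(C = C, passes = passes),
            seed, d)
}

# ---- list-wise: AdaRank ----------------------------------------------------

#' AdaRank: boosting on a list-wise performance measure
#'
#' Boosts over queries rather than instances: maintains query weights P
#' (initialized uniform); weak rankers are single raw features (score =
#' feature value); each round selects the feature maximizing
#' \code{sum_q P(q) E(q)} where E(q) is the NDCG@k of that feature's
#' induced ranking of query q, sets
#' \code{alpha = 0.5 log(sum_q P(q)(1 + E(q)) / sum_q P(q)(1 - E(q)))},
#' and reweights queries proportional to \code{exp(-NDCG@k)} of the current
#' ensemble so poorly-ranked queries gain influence. The final score is the
#' alpha-weighted sum of the selected features.
#'
#' @param groups list of \linkS4class{RankingGroup}.
#' @param rounds boosting rounds (default 100).
#' @param k NDCG truncation depth used as the boosting criterion
#'   (default 10).
#' @param trace record the query weights after every round in
#'   \code{params$PTrace} (diagnostic; default FALSE).
#' @return fitted \linkS4class{RankerModel}; params carry \code{feature}
#'   and \code{alpha}.
#' @export
fitAdaRank <- function(groups, rounds = 100L, k = 10L, trace = FALSE) {
  nq <- length(groups)
  if (!nq) stop("no training groups")
  if (all(vapply(groups, function(g) all(g@grades == 0L) ||
                   length(unique(g@grades)) < 2L, logical(1))))
    stop("all groups are degenerate (no ranking signal)")
  d <- ncol(groups[[1L]]@features)
  E <- matrix(0, nq, d)                       # NDCG@k of each feature ranking
  for (q in seq_len(nq)) {
    g <- groups[[q]]
    for (f in seq_len(d))
      E[q, f] <- ndcgFromScores(g@features[, f], g@grades, g@compoundIds, k)
  }
  P <- rep(1 / nq, nq)
  feat <- alp <- numeric(0)
  PTrace <- list()
  ens <- lapply(groups, function(g) numeric(nrow(g@features)))
  for (t in seq_len(rounds)) {
    crit <- drop(P %*% E)
    f <- which.max(crit)
    wsum <- sum(P * (1 + E[, f])); wdif <- sum(P * (1 - E[, f]))
    if (wdif <= 0) wdif <- 1e-10
    a <- 0.5 * log(wsum / wdif)
    feat <- c(feat, f); alp <- c(alp, a)
    ens <- lapply(seq_len(nq), function(q)
      ens[[q]] + a * groups[[q]]@features[, f])
    ndcgEns <- vapply(seq_len(nq), function(q)
      ndcgFromScores(ens[[q]], groups[[q]]@grades,
                     groups[[q]]@compoundIds, k), numeric(1))
    P <- exp(-ndcgEns)
    P <- P / sum(P)
    if (trace) PTrace[[length(PTrace) + 1L]] <- P
  }
  params <- list(feature = as.integer(feat), alpha = alp)
  if (trace) params$PTrace <- PTrace
  .newModel("adarank", params, list(rounds = rounds, k = k), NA_integer_, d)
}

# ---- list-wise: ListNet ----------------------------------------------------

#' ListNet: list-wise ranking with top-one probabilities
#'
#' Linear scorer trained on the cross entropy between the target top-one
#' distribution \code{P_y(j) = exp(y_j) / sum_k exp(y_k)} over a query's
#' grades and the model distribution \code{P_f(j) = softmax(f(x_j))}:
#' \deqn{L = -\sum_q \sum_j P_y(j) \log P_f(j).}
#' Full-batch gradient descent with seeded initialization and step halving
#' (non-increasing loss). Queries with a single item carry no list
#' information and are skipped with a message.
#'
#' @param groups list of \linkS4class{RankingGroup} (>= 2 items each to
#'   contribute).
#' @param learningRate initial step (default 0.01).
#' @param epochs gradient steps (default 200).
#' @param seed RNG seed for initialization.
#' @return fitted \linkS4class{RankerModel} with params \code{w} and the
#'   \code{loss} trace.
#' @export
fitListNet <- function(groups, learningRate = 0.01, epochs = 200L, seed = 1L) {
  sizes <- vapply(groups, function(g) length(g@grades), integer(1))
  if (any(sizes < 2L)) {
    message(sum(sizes < 2L), " single-item group(s) skipped (zero gradient)")
    groups <- groups[sizes >= 2L]
  }
  if (!length(groups)) stop("no usable groups")
  d <- ncol(groups[[1L]]@features)
  Py <- lapply(groups, function(g) {
    e <- exp(g@grades - max(g@grades)); e / sum(e)
  })
  set.seed(seed)
  w <- stats::rnorm(d, sd = 0.01)
  lossGrad <- function(w, wantGrad = TRUE) {
    L <- 0; gr <- numeric(d)
    for (q in seq_along(groups)) {
      Xq <- groups[[q]]@features
      f <- drop(Xq %*% w)
      f <- f - max(f)
      Pf <- exp(f) / sum(exp(f))
      L <- L - sum(Py[[q]] * (f - log(sum(exp(f)))))
      if (wantGrad) gr <- gr + drop(crossprod(Xq, Pf - Py[[q]]))
    }
    list(L = L, gr = gr)
  }
  cur <- lossGrad(w)
  trace <- numeric(epochs)
  lr <- learningRate
  for (ep in seq_len(epochs)) {
    repeat {
      w2 <- w - lr * cur$gr
      nxt <- lossGrad(w2)
      if (nxt$L <= cur$L || lr < 1e-12) break
      lr <- lr / 2
    }
    if (nxt$L <= cur$L) { w <- w2; cur <- nxt }
    trace[ep] <- cur$L
  }
  .newModel("listnet", list(w = w, loss = trace),
            list(learningRate = learningRate, epochs = epochs), seed, d)
}

#' ListNet top-one cross-entropy loss
#'
#' Evaluates the list-wise loss minimized by [fitListNet()] for a given
#' linear weight vector (\code{listnetLoss}) or for precomputed per-query
#' score vectors (\code{listnetLossFromScores}); exposed so the loss
#' surface is auditable independently of the optimizer.
#'
#' @param w linear weight vector.
#' @param groups list of \linkS4class{RankingGroup}.
#' @return the summed cross-entropy loss.
#' @export
listnetLoss <- function(w, groups) {
  listnetLossFromScores(lapply(groups, function(g)
    drop(g@features %*% w)), groups)
}

#' @rdname listnetLoss
#' @param scores list of numeric score vectors aligned with \code{groups}.
#' @export
listnetLossFromScores <- function(scores, groups) {
  L <- 0
  for (q in seq_along(groups)) {
    g <- groups[[q]]
    if (length(g@grades) < 2L) next
    ey <- exp(g@grades - max(g@grades))
    Py <- ey / sum(ey)
    f <- scores[[q]] - max(scores[[q]])
    L <- L - sum(Py * (f - log(sum(exp(f)))))
  }
  L
}

# ---- baseline: epsilon-SVR -------------------------------------------------

#' Support-vector-regression baseline
#'
#' The traditional regression-style screening baseline: pools every
#' (feature, grade) instance across queries and fits epsilon-insensitive
#' support-vector regression (delegated to \pkg{e1071}/libsvm). The score
#' of a compound is its predicted grade. The support vectors and dual
#' coefficients are retained so scoring is self-contained and the model is
#' JSON-serializable like every other ranker.
#'
#' @param groups list of \linkS4class{RankingGroup}.
#' @param cost,epsilon,gamma libsvm hyperparameters; \code{gamma} defaults
#'   to 1/d.
#' @param kernel \code{"radial"} (default) or \code{"linear"}.
#' @return fitted \linkS4class{RankerModel}.
#' @export
fitSVRBaseline <- function(groups, cost = 1, epsilon = 0.1, gamma = NULL,
                           kernel = c("radial", "linear")) {
  kernel <- match.arg(kernel)
  pool <- .poolGroups(groups)
  if (length(unique(pool$grades)) < 2L)
    stop("degenerate training set: a single grade cannot be regressed")
  d <- ncol(pool$X)
  if (is.null(gamma)) gamma <- 1 / d
  fit <- e1071::svm(pool$X, pool$grades, type = "eps-regression",
                    kernel = kernel, cost = cost, epsilon = epsilon,
                    gamma = gamma, scale = FALSE)
  .newModel("svr_baseline",
            list(SV = unname(as.matrix(fit$SV)),
                 coefs = drop(fit$coefs), rho = fit$rho,
                 gamma = gamma, kernel = kernel),
            list(cost = cost, epsilon = epsilon), NA_integer_, d)
}

.svrScore <- function(p, X) {
  K <- if (p$kernel == "linear") X %*% t(p$SV)
       else {
         d2 <- outer(rowSums(X^2), rowSums(p$SV^2), "+") - 2 * X %*% t(p$SV)
         exp(-p$gamma * pmax(d2, 0))
       }
  drop(K %*% p$coefs) - p$rho
}

# ---- serialization ---------------------------------------------------------

#' Serialize a RankerModel to JSON
#'
#' Full-precision JSON round-trip: \code{readRankerModel(writeRankerModel(m))}
#' scores identically to \code{m}.
#'
#' @param model a fitted \linkS4class{RankerModel}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeRankerModel <- function(model, path) {
  stopifnot(is(model, "RankerModel"))
  pl <- model@params
  pl <- lapply(pl, function(p) if (is.matrix(p))
    list(.matrix = TRUE, nrow = nrow(p), data = as.numeric(p)) else p)
  jsonlite::write_json(
    list(algorithm = model@algorithm, params = pl, hyper = model@hyper,
         seed = model@seed, dim = model@dim, fitted = model@fitted),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname writeRankerModel
#' @export
readRankerModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  pl <- lapply(j$params, function(p) {
    if (is.list(p) && isTRUE(p$.matrix))
      matrix(as.numeric(p$data), nrow = p$nrow)
    else p
  })
  if (!is.null(pl$feature)) pl$feature <- as.integer(pl$feature)
  new("RankerModel", algorithm = j$algorithm, params = pl,
      hyper = as.list(j$hyper),
      seed = if (is.null(j$seed)) NA_integer_ else as.integer(j$seed),
      dim = as.integer(j$dim), fitted = isTRUE(j$fitted))
}
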