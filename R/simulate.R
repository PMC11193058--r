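#' Construct a simulation design
#'
#' Defaults reproduce the benchmark conditions used throughout the package:
#' n = 300 samples, p = 200 leaf features on a depth-5 random taxonomy,
#' q = 30 responses, rank-3 coefficient matrix with singular values (4, 3, 2),
#' 5\% of features carrying signal, and signal-to-noise ratio 0.5 under the
#' weakest-layer convention. The count surrogate is a zero-inflated lognormal
#' with Beta(1.2, 2.8) per-feature prevalence, lognormal feature locations
#' (mu 0, sd 1.5), unit per-sample lognormal scale, and mean sequencing depth
#' 5e4, chosen to give prevalence and variance profiles qualitatively like
#' stool metagenomes.
#'
#' @param n,p,q,m sample, leaf-feature, response and covariate counts
#'   (m includes the intercept).
#' @param setting which feature set carries signal: "a" high-variation
#'   leaves, "b" rare leaves, "c" any leaves, "d" internal nodes.
#' @param rank,d true rank and singular values.
#' @param signalFraction fraction of features in the union of u-supports.
#' @param vFraction fraction of responses in each component's v-support.
#' @param snr signal-to-noise ratio.
#' @param treeDepth maximum taxonomy depth.
#' @param zeroInflA,zeroInflB,mu0,sigma0,sigma1,meanDepth count-surrogate
#'   parameters.
#' @param seed integer seed.
#' @return a \linkS4class{SimulationDesign}.
#' @export
simulationDesign <- function(n = 300, p = 200, q = 30, m = 2,
                             setting = "a", rank = 3, d = c(4, 3, 2),
                             signalFraction = 0.05, vFraction = 0.2,
                             snr = 0.5, treeDepth = 5,
                             zeroInflA = 1.2, zeroInflB = 2.8,
                             mu0 = 0, sigma0 = 1.5, sigma1 = 1,
                             meanDepth = 5e4, seed = 1) {
  new("SimulationDesign", n = as.integer(n), p = as.integer(p),
      q = as.integer(q), m = as.integer(m), setting = setting,
      rank = as.integer(rank), d = as.numeric(d),
      signalFraction = signalFraction, vFraction = vFraction, snr = snr,
      treeDepth = as.integer(treeDepth), zeroInflA = zeroInflA,
      zeroInflB = zeroInflB, mu0 = mu0, sigma0 = sigma0, sigma1 = sigma1,
      meanDepth = meanDepth, seed = as.integer(seed))
}

# run expr with a locally seeded, explicitly versioned RNG; the caller's RNG
# state is untouched
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

#' Simulate a random taxonomy with exactly p leaves
#'
#' Recursively partitions the leaf set: each internal node at depth below
#' \code{treeDepth} splits its leaves into 2-4 children with random sizes;
#' singleton groups attach as leaves. Unary chains are collapsed during tree
#' construction.
#'
#' @param p number of leaves.
#' @param treeDepth maximum depth.
#' @param seed integer seed.
#' @param leafIds leaf labels (default \code{taxon001, ...}).
#' @return an \code{ape} \code{phylo} with p tips.
#' @export
simulateTree <- function(p, treeDepth = 5, seed = 1,
                         leafIds = sprintf("taxon%03d", seq_len(p))) {
  stopifnot(p >= 2, length(leafIds) == p)
  .withSeed(seed, {
    lineages <- vector("list", p)
    names(lineages) <- leafIds
    counter <- 0L
    recurse <- function(idx, depth, prefix) {
      if (length(idx) == 1 && depth > 1) {
        lineages[[idx]] <<- prefix
        return(invisible(NULL))
      }
      if (depth > treeDepth) {
        for (i in idx) lineages[[i]] <<- prefix
        return(invisible(NULL))
      }
      k <- min(length(idx), sample(2:4, 1))
      groups <- split(idx, sort(rep_len(seq_len(k), length(idx))[
        sample.int(length(idx))]))
      for (g in groups) {
        counter <<- counter + 1L
        recurse(g, depth + 1L, c(prefix, sprintf("clade%04d", counter)))
      }
      invisible(NULL)
    }
    recurse(seq_len(p), 1L, character(0))
    treeFromLineages(lineages)
  })
}

#' Simulate zero-inflated compositional count data
#'
#' Parametric surrogate for template-based microbiome count simulators:
#' per-feature prevalence \code{pi_j ~ Beta(a0, b0)}, per-feature lognormal
#' location \code{mu_j ~ N(mu0, sigma0^2)}, per-sample latent abundance
#' \code{lambda_ij = Bernoulli(pi_j) LogNormal(mu_j, sigma1^2)}, sequencing
#' depth \code{depth_i ~ LogNormal} with the requested mean, and counts
#' \code{w_ij ~ Poisson(depth_i lambda_ij / sum_j lambda_ij)}. Rows are
#' guaranteed at least one nonzero count.
#'
#' @param design a \linkS4class{SimulationDesign}.
#' @param seed integer seed (defaults to the design's seed).
#' @return list with \code{counts} (n x p integer matrix) and \code{meta}
#'   (data.frame of per-feature prevalence and location parameters).
#' @export
simulateCounts <- function(design, seed = design@seed) {
  n <- design@n
  p <- design@p
  .withSeed(seed, {
    pi <- stats::rbeta(p, design@zeroInflA, design@zeroInflB)
    mu <- stats::rnorm(p, design@mu0, design@sigma0)
    sdDepth <- 0.3
    depth <- stats::rlnorm(n, log(design@meanDepth) - sdDepth^2 / 2, sdDepth)
    lam <- matrix(stats::rbinom(n * p, 1, rep(pi, each = n)), n, p) *
      matrix(stats::rlnorm(n * p, rep(mu, each = n), design@sigma1), n, p)
    for (i in which(rowSums(lam) == 0)) {
      while (sum(lam[i, ]) == 0) {
        lam[i, ] <- stats::rbinom(p, 1, pi) *
          stats::rlnorm(p, mu, design@sigma1)
      }
    }
    rate <- lam / rowSums(lam) * depth
    w <- matrix(stats::rpois(n * p, rate), n, p)
    for (i in which(rowSums(w) == 0)) {
      while (sum(w[i, ]) == 0) w[i, ] <- stats::rpois(p, rate[i, ])
    }
    dimnames(w) <- list(sprintf("sample%03d", seq_len(n)),
                        sprintf("taxon%03d", seq_len(p)))
    list(counts = w,
         meta = data.frame(feature = colnames(w), prevalence = pi, mu = mu))
  })
}

#' Simulate sparse low-rank coefficient structure
#'
#' Places the union of the left-vector supports on \code{signalFraction * p}
#' eligible nodes (eligibility depends on the design setting: top-quartile
#' variance leaves, bottom-quartile prevalence leaves, any leaves, or internal
#' nodes), partitioned disjointly across the rank components. Support entries
#' are drawn as \code{sign * Uniform(0.5, 1)}, projected within the support
#' onto the zero-sum constraint null space, and normalized; disjoint supports
#' make the left vectors exactly orthogonal (a Gram-Schmidt pass is applied
#' as a safeguard). Right vectors are sparse (\code{vFraction} of responses
#' per component, disjoint when possible) and unit norm.
#'
#' @param design a \linkS4class{SimulationDesign}.
#' @param A an \linkS4class{AncestryMatrix}.
#' @param x log relative abundance matrix (leaf columns, for variance
#'   ranking).
#' @param counts count matrix (for prevalence ranking).
#' @param seed integer seed.
#' @return list with \code{beta}, \code{U}, \code{V}, \code{d}, \code{Gamma},
#'   \code{C}.
#' @export
simulateCoefficients <- function(design, A, x, counts,
                                 seed = design@seed + 1L) {
  p <- design@p
  r <- design@rank
  q <- design@q
  P <- length(A@nodeIds)
  cvec <- constraintVector(A)
  nSignal <- max(2 * r, round(design@signalFraction * p))
  sizes <- diff(round(seq(0, nSignal, length.out = r + 1)))
  sizes <- pmax(sizes, 2)

  leafCols <- which(A@isLeaf)
  # top/bottom quartile of the ranking criterion, widened to the best
  # sum(sizes) nodes when a small p makes the quartile too narrow
  nNeed <- sum(sizes)
  eligible <- switch(design@setting,
    a = {
      vars <- apply(x, 2, stats::var)
      keep <- vars >= stats::quantile(vars, 0.75)
      leafCols[keep | rank(-vars, ties.method = "first") <= nNeed]
    },
    b = {
      prev <- colMeans(counts > 0)
      keep <- prev <= stats::quantile(prev, 0.25)
      leafCols[keep | rank(prev, ties.method = "first") <= nNeed]
    },
    c = leafCols,
    d = which(!A@isLeaf)
  )
  if (length(eligible) < sum(sizes)) {
    stop("not enough eligible nodes (", length(eligible),
         ") for the requested signal size (", sum(sizes), ")")
  }

  .withSeed(seed, {
    picked <- sample(eligible, sum(sizes))
    supports <- split(picked, rep(seq_len(r), sizes))
    U <- matrix(0, P, r, dimnames = list(A@nodeIds, NULL))
    for (k in seq_len(r)) {
      repeat {
        uk <- rep(0, P)
        s <- supports[[k]]
        uk[s] <- sample(c(-1, 1), length(s), replace = TRUE) *
          stats::runif(length(s), 0.5, 1)
        uk <- .projectSupport(uk, cvec)
        if (sqrt(sum(uk^2)) > 1e-6) break
      }
      U[, k] <- uk / sqrt(sum(uk^2))
    }
    # Gram-Schmidt safeguard (no-op for disjoint supports)
    for (k in seq_len(r)[-1]) {
      for (i in seq_len(k - 1)) {
        U[, k] <- U[, k] - sum(U[, i] * U[, k]) * U[, i]
      }
      U[, k] <- .projectSupport(U[, k], cvec)
      U[, k] <- U[, k] / sqrt(sum(U[, k]^2))
    }

    vSize <- max(1, round(design@vFraction * q))
    V <- matrix(0, q, r)
    if (vSize * r <= q) {
      vPicked <- sample(q, vSize * r)
      vSupports <- split(vPicked, rep(seq_len(r), each = vSize))
    } else {
      vSupports <- lapply(seq_len(r), function(k) sample(q, vSize))
    }
    for (k in seq_len(r)) {
      vk <- rep(0, q)
      s <- vSupports[[k]]
      vk[s] <- sample(c(-1, 1), length(s), replace = TRUE) *
        stats::runif(length(s), 0.5, 1)
      V[, k] <- vk / sqrt(sum(vk^2))
    }
    for (k in seq_len(r)[-1]) {
      for (i in seq_len(k - 1)) {
        V[, k] <- V[, k] - sum(V[, i] * V[, k]) * V[, i]
      }
      V[, k] <- V[, k] / sqrt(sum(V[, k]^2))
    }
    for (k in seq_len(r)) {
      if (V[which.max(abs(V[, k])), k] < 0) {
        V[, k] <- -V[, k]
        U[, k] <- -U[, k]
      }
    }

    beta <- matrix(stats::rnorm(design@m * q), design@m, q)
    Gamma <- U %*% (design@d * t(V))
    C <- A@a %*% Gamma
    list(beta = beta, U = U, V = V, d = design@d, Gamma = Gamma, C = C)
  })
}

#' Simulate the response matrix at an exact signal-to-noise ratio
#'
#' Draws an i.i.d. Gaussian error matrix and rescales it so the achieved
#' ratio matches \code{design@snr} exactly. The default "weakest" convention
#' sets \code{snr = d_r ||Xtilde u_r v_r'||_F / ||E||_F} with \code{d_r} the
#' smallest true singular value, i.e. noise is calibrated against the weakest
#' signal layer; \code{"total"} uses \code{||Xtilde Gamma||_F / ||E||_F}.
#'
#' @param design a \linkS4class{SimulationDesign}.
#' @param z covariate matrix.
#' @param beta true covariate effects.
#' @param xtilde aggregated design.
#' @param coefs list from [simulateCoefficients()].
#' @param snrDef "weakest" or "total".
#' @param seed integer seed.
#' @return list with \code{y} and \code{E}.
#' @export
simulateResponse <- function(design, z, beta, xtilde, coefs,
                             snrDef = c("weakest", "total"),
                             seed = design@seed + 2L) {
  snrDef <- match.arg(snrDef)
  r <- design@rank
  signal <- if (snrDef == "weakest") {
    coefs$d[r] * sqrt(sum((xtilde %*% coefs$U[, r])^2)) *
      sqrt(sum(coefs$V[, r]^2))
  } else {
    sqrt(sum((xtilde %*% coefs$Gamma)^2))
  }
  .withSeed(seed, {
    E0 <- matrix(stats::rnorm(design@n * design@q), design@n, design@q)
    E <- E0 * (signal / (design@snr * sqrt(sum(E0^2))))
    y <- z %*% beta + xtilde %*% coefs$Gamma + E
    dimnames(y) <- list(rownames(xtilde),
                        sprintf("resp%03d", seq_len(design@q)))
    dimnames(E) <- dimnames(y)
    list(y = y, E = E)
  })
}

#' Generate one complete synthetic microbiome-metabolome dataset
#'
#' Orchestrates [simulateTree()], [simulateCounts()],
#' [simulateCoefficients()] and [simulateResponse()] under sub-seeds derived
#' from the design seed, and returns every intermediate object needed to fit
#' and score models, including the exact error matrix (so
#' \code{y - z beta - xtilde Gamma = E} holds exactly).
#'
#' @param design a \linkS4class{SimulationDesign}.
#' @param snrDef SNR convention, see [simulateResponse()].
#' @return list with design echo, counts, tree, ancestry A, x, xtilde, cvec,
#'   z, truth (beta, U, V, d, Gamma, C), y and E.
#' @export
simulateDataset <- function(design, snrDef = c("weakest", "total")) {
  snrDef <- match.arg(snrDef)
  tree <- simulateTree(design@p, design@treeDepth, seed = design@seed + 3L)
  cw <- simulateCounts(design)
  w <- cw$counts
  x <- tssLogTransform(w)
  A <- buildAncestryMatrix(tree, leafOrder = colnames(w))
  xt <- aggregateFeatures(x, A)
  z <- .withSeed(design@seed + 4L, {
    z <- cbind(1, matrix(stats::rnorm(design@n * (design@m - 1)),
                         design@n, design@m - 1))
    dimnames(z) <- list(rownames(w),
                        c("(Intercept)",
                          if (design@m > 1) sprintf("cov%d",
                                                    seq_len(design@m - 1))))
    z
  })
  coefs <- simulateCoefficients(design, A, x, w)
  resp <- simulateResponse(design, z, coefs$beta, xt, coefs, snrDef = snrDef)
  list(design = design, counts = w, tree = tree, A = A, x = x, xtilde = xt,
       cvec = constraintVector(A), z = z, truth = coefs, y = resp$y,
       E = resp$E)
}
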