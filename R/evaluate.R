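#' Estimation and prediction error of a coefficient estimate
#'
#' Frobenius norms \code{||Chat - C||_F} (coefficient estimation error) and
#' \code{||X Chat - X C||_F} (prediction error on the leaf design).
#'
#' @param Chat,Ctrue estimated and true leaf-level coefficient matrices.
#' @param x leaf-level design matrix.
#' @return list with \code{erC} and \code{erXC}.
#' @export
estimationErrors <- function(Chat, Ctrue, x) {
  if (!all(dim(Chat) == dim(Ctrue))) stop("coefficient shapes differ")
  if (ncol(x) != nrow(Ctrue)) stop("design and coefficient shapes differ")
  delta <- Chat - Ctrue
  list(erC = sqrt(sum(delta^2)), erXC = sqrt(sum((x %*% delta)^2)))
}

#' Align estimated components to the truth
#'
#' Sequential extraction need not return components in the true order (or
#' sign). Greedy matching maximizing the absolute cosine between estimated
#' and true left vectors, each true component used at most once; signs are
#' chosen to make the matched cosines positive.
#'
#' @param Uhat,Utrue matrices of estimated / true left vectors (columns).
#' @return data.frame with one row per true component: \code{trueIdx},
#'   \code{estIdx} (NA if unmatched), \code{sign}, \code{cosine}.
#' @export
alignComponents <- function(Uhat, Utrue) {
  rT <- ncol(Utrue)
  rE <- ncol(Uhat)
  if (rT == 0) stop("no true components to align to")
  out <- data.frame(trueIdx = seq_len(rT), estIdx = NA_integer_,
                    sign = NA_real_, cosine = NA_real_)
  if (rE == 0) return(out)
  nrmE <- sqrt(colSums(Uhat^2))
  nrmT <- sqrt(colSums(Utrue^2))
  cosMat <- crossprod(Uhat, Utrue) / (pmax(nrmE, 1e-300) %o%
                                        pmax(nrmT, 1e-300))
  absCos <- abs(cosMat)
  for (step in seq_len(min(rT, rE))) {
    ij <- which(absCos == max(absCos), arr.ind = TRUE)[1, ]
    i <- ij[1]
    j <- ij[2]
    out$estIdx[j] <- i
    out$sign[j] <- sign(cosMat[i, j])
    out$cosine[j] <- absCos[i, j]
    absCos[i, ] <- -Inf
    absCos[, j] <- -Inf
  }
  out
}

#' Support-recovery false positive and false negative rates
#'
#' Components are aligned first ([alignComponents()]); entries of all aligned
#' left and right vectors are then pooled. An entry is a true positive when
#' its absolute true value exceeds \code{zeroTol}. Estimated components with
#' no true counterpart contribute all their nonzeros as false positives;
#' missing components contribute all their true nonzeros as false negatives.
#'
#' @param Uhat,Vhat estimated factor matrices.
#' @param Utrue,Vtrue true factor matrices.
#' @param zeroTol magnitude below which an entry counts as zero.
#' @return list with \code{fpr}, \code{fnr}, the pooled denominators
#'   \code{nTrueZero} and \code{nTrueNonzero}, per-component rates, and the
#'   alignment table.
#' @export
selectionRates <- function(Uhat, Vhat, Utrue, Vtrue, zeroTol = 1e-8) {
  al <- alignComponents(Uhat, Utrue)
  P <- nrow(Utrue)
  q <- nrow(Vtrue)
  estPool <- truePool <- numeric(0)
  perComp <- list()
  for (k in seq_len(ncol(Utrue))) {
    j <- al$estIdx[k]
    ue <- if (is.na(j)) rep(0, P) else Uhat[, j]
    ve <- if (is.na(j)) rep(0, q) else Vhat[, j]
    estPool <- c(estPool, ue, ve)
    truePool <- c(truePool, Utrue[, k], Vtrue[, k])
    tnz <- c(abs(Utrue[, k]), abs(Vtrue[, k])) > zeroTol
    enz <- c(abs(ue), abs(ve)) > zeroTol
    perComp[[k]] <- data.frame(
      trueIdx = k, estIdx = j,
      fpr = if (sum(!tnz) > 0) sum(enz & !tnz) / sum(!tnz) else NA_real_,
      fnr = if (sum(tnz) > 0) sum(!enz & tnz) / sum(tnz) else NA_real_)
  }
  extra <- setdiff(seq_len(ncol(Uhat)), al$estIdx)
  for (j in extra) {
    estPool <- c(estPool, Uhat[, j], Vhat[, j])
    truePool <- c(truePool, rep(0, P + q))
  }
  trueNZ <- abs(truePool) > zeroTol
  estNZ <- abs(estPool) > zeroTol
  nTrueZero <- sum(!trueNZ)
  nTrueNonzero <- sum(trueNZ)
  list(
    fpr = if (nTrueZero > 0) sum(estNZ & !trueNZ) / nTrueZero else NA_real_,
    fnr = if (nTrueNonzero > 0) {
      sum(!estNZ & trueNZ) / nTrueNonzero
    } else NA_real_,
    nTrueZero = nTrueZero, nTrueNonzero = nTrueNonzero,
    perComponent = do.call(rbind, perComp), alignment = al)
}

#' Score one fitted model against simulated truth
#'
#' @param fit a \linkS4class{TreeFarFit} or \linkS4class{CrrrFit} with
#'   \code{Chat} assembled.
#' @param data a dataset from [simulateDataset()].
#' @param zeroTol zero tolerance for support recovery.
#' @return one-row data.frame with erC, erXC, fpr, fnr and rankHat.
#' @export
evaluateFit <- function(fit, data, zeroTol = 1e-8) {
  err <- estimationErrors(coefC(fit), data$truth$C, data$x)
  sel <- selectionRates(leftVectors(fit), rightVectors(fit),
                        data$truth$U, data$truth$V, zeroTol = zeroTol)
  data.frame(erC = err$erC, erXC = err$erXC, fpr = sel$fpr, fnr = sel$fnr,
             rankHat = estimatedRank(fit))
}

#' Replicated benchmark of the sparse factor regression and the dense
#' baseline
#'
#' Generates \code{nReps} seeded datasets from the design, fits each
#' requested method, scores estimation error, prediction error and support
#' recovery, and returns a tidy table with one row per replicate and method.
#' Replicate failures are caught, reported as a warning, and excluded.
#'
#' @param design a \linkS4class{SimulationDesign}; the per-replicate seed is
#'   \code{baseSeed + 10 * replicate}.
#' @param methods subset of \code{c("treefar", "crrr")}.
#' @param nReps number of replicates.
#' @param baseSeed integer base seed.
#' @param maxRank maximum rank given to the sparse fit (default true rank
#'   plus one, so rank termination is exercised).
#' @param crrrRank rank given to the dense baseline (default true rank).
#' @param penalty a [penaltySpec()].
#' @param snrDef SNR convention.
#' @return data.frame with columns rep, seed, method, erC, erXC, fpr, fnr,
#'   rankHat, elapsed.
#' @export
runReplicates <- function(design, methods = c("treefar", "crrr"), nReps = 20,
                          baseSeed = design@seed,
                          maxRank = design@rank + 1L,
                          crrrRank = design@rank,
                          penalty = penaltySpec(),
                          snrDef = c("weakest", "total")) {
  snrDef <- match.arg(snrDef)
  methods <- match.arg(methods, c("treefar", "crrr"), several.ok = TRUE)
  stopifnot(nReps >= 1)
  rows <- list()
  failures <- 0L
  for (rep in seq_len(nReps)) {
    seed <- as.integer(baseSeed + 10L * rep)
    des <- design
    des@seed <- seed
    data <- simulateDataset(des, snrDef = snrDef)
    for (method in methods) {
      t0 <- proc.time()[["elapsed"]]
      res <- tryCatch({
        fit <- if (method == "treefar") {
          f <- fitSequentialFactors(data$y, data$xtilde, data$z, data$cvec,
                                    maxRank = maxRank, penalty = penalty)
          assembleC(f, data$A)
        } else {
          assembleC(fitCrrr(data$y, data$xtilde, data$z, data$cvec,
                            rank = crrrRank), data$A)
        }
        evaluateFit(fit, data)
      }, error = function(e) {
        warning("replicate ", rep, " method ", method, " failed: ",
                conditionMessage(e))
        NULL
      })
      if (is.null(res)) {
        failures <- failures + 1L
        next
      }
      res$rep <- rep
      res$seed <- seed
      res$method <- method
      res$elapsed <- proc.time()[["elapsed"]] - t0
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("rep", "seed", "method", "erC", "erXC", "fpr", "fnr",
                 "rankHat", "elapsed")]
  attr(out, "failures") <- failures
  out
}

#' Per-method summary of a replicate table
#'
#' @param results table from [runReplicates()].
#' @return data.frame of per-method means and quartiles of each metric.
#' @export
summarizeReplicates <- function(results) {
  metrics <- c("erC", "erXC", "fpr", "fnr", "rankHat")
  do.call(rbind, lapply(split(results, results$method), function(df) {
    out <- data.frame(method = df$method[1], n = nrow(df))
    for (mm in metrics) {
      v <- df[[mm]]
      out[[paste0(mm, "_mean")]] <- mean(v, na.rm = TRUE)
      out[[paste0(mm, "_q1")]] <- unname(stats::quantile(v, 0.25,
                                                         na.rm = TRUE))
      out[[paste0(mm, "_q3")]] <- unname(stats::quantile(v, 0.75,
                                                         na.rm = TRUE))
    }
    out
  }))
}
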