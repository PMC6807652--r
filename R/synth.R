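#' Build a synthetic-cohort configuration
#'
#' Returns a [SynthConfig-class] whose defaults mirror the emulated study
#' design: 13 subjects, each recorded under two conditions (rested
#' wakefulness RW, sleep restriction SR) at four times of day (10:00,
#' 14:00, 18:00, 22:00), with 116 regions in six functional modules and
#' 840 timepoints per recording (a ~42 min task at TR = 3 s).
#'
#' The generative model is a latent-signal model. Each recording draws a
#' global AR(1) series `g(t)`, one AR(1) module series `u_k(t)` per
#' module, and one AR(1) hub series `h(t)`; all series (including the
#' regional noise) share the lag-1 autocorrelation `arCoefficient`, the
#' simplest surrogate for BOLD autocorrelation at TR = 3 s. The module
#' signal is `m_k = gamma g + sqrt(1 - gamma^2) u_k` with
#' `gamma = betweenCoupling`, so `gamma` sets the inter-module coherence.
#' A non-hub region in module k is
#' `x_i = w m_k + sqrt(1 - w^2) eps_i` with `w = withinCoupling`, giving
#' within-module correlation `w^2` and between-module correlation
#' `w^2 gamma^2`. The designated hub region of each module (its first
#' region) carries two extra loadings: a constant `hubBoost` on the
#' module-specific signal `u_k`, which makes hubs the top-degree nodes
#' of their modules without leaking correlation across modules, and a
#' loading `hubCoupling` on the shared hub series `h`, which
#' inter-correlates the six hubs so they form a mutually connected
#' high-degree club in the thresholded networks. All regional variances
#' are normalised to 1, so couplings translate directly into
#' correlations.
#'
#' Two effects are planted at the coupling level so they must survive the
#' whole pipeline to be detected:
#' \describe{
#'   \item{condition}{in SR, `gamma` is scaled by `1 - conditionEffect`.
#'     Between-module correlations drop while within-module correlations
#'     are untouched, so at fixed density the thresholded SR network
#'     retains fewer inter-module shortcuts and its characteristic path
#'     length rises.}
#'   \item{time of day}{two components. First, the hub-to-hub coupling
#'     is scaled by `1 - timeEffect (s - 1)`, `s = 1..4`: the mutually
#'     connected hub club dissolves over the day, giving the six hub
#'     regions -- and only them -- a nodal signature of the time factor
#'     that region-flagging must recover. Second, a degree-neutral
#'     mixing rotation drives the global assortativity decline: each
#'     module contributes an equal-size connector block (see
#'     [connectorBlocks()]) whose region-to-region wirings are, slot by
#'     slot across the four sessions, reassigned from pairing
#'     degree-similar modules in the first session to pairing
#'     degree-dissimilar modules in the last, always at the same planted
#'     correlation `bridgeCoupling`. The identity of a
#'     connector's partners changes while its expected degree does not,
#'     so high-degree/high-degree edges are progressively replaced by
#'     high/low edges and degree assortativity declines across the day
#'     in both conditions without planting nodal degree effects outside
#'     the hubs.}
#' }
#'
#' @param nSubjects,nRegions,nTimepoints,trSeconds design dimensions.
#' @param moduleSizes integer vector of module sizes summing to
#'   `nRegions`; with the default 116-region layout the sizes and the
#'   region-to-module map come from the packaged node table.
#' @param withinCoupling,betweenCoupling,hubCoupling,hubBoost,arCoefficient
#'   generative-model amplitudes, see Details.
#' @param bridgeCoupling,bridgeBlockSize,blockContrast connector-block
#'   rotation parameters, see Details and [connectorBlocks()]; set
#'   `bridgeCoupling = 0` to disable the rotation (it is only active for
#'   six-module designs).
#' @param moduleContrast optional relative within-coupling contrast
#'   between the largest and smallest modules (default 0, i.e. all
#'   modules equally coherent).
#' @param conditionEffect,timeEffect planted effect sizes, see Details.
#' @param subjectSd between-subject coefficient of variation applied to
#'   the couplings (constant within a subject across all 8 recordings).
#' @param seed master RNG seed.
#' @param nodeTable node table supplying region labels and module
#'   membership when `nRegions = 116`.
#' @return a validated [SynthConfig-class].
#' @seealso [generateCohort()]
#' @export
synthConfig <- function(nSubjects = 13, nRegions = 116, nTimepoints = 840,
                        trSeconds = 3.0, moduleSizes = NULL,
                        withinCoupling = 0.6, betweenCoupling = 0.9,
                        hubCoupling = 0.5, hubBoost = 0.25,
                        bridgeCoupling = 0.42, bridgeBlockSize = 12,
                        blockContrast = 0.26, moduleContrast = 0,
                        arCoefficient = 0.3,
                        conditionEffect = 0.15, timeEffect = 1/3,
                        subjectSd = 0.05, seed = 1L,
                        nodeTable = NULL) {
  nRegions <- as.integer(nRegions)
  if (nRegions == 116L && is.null(moduleSizes)) {
    if (is.null(nodeTable)) nodeTable <- aalNodeTable()
    moduleOf <- match(nodeTable$module, .MODULES)
    moduleSizes <- as.integer(table(factor(nodeTable$module,
                                           levels = .MODULES)))
    names(moduleSizes) <- .MODULES
    labels <- nodeTable$region_label
  } else {
    if (is.null(moduleSizes))
      stop("moduleSizes must be given when nRegions != 116")
    moduleSizes <- as.integer(moduleSizes)
    if (sum(moduleSizes) != nRegions)
      stop("moduleSizes must sum to nRegions")
    if (is.null(names(moduleSizes)))
      names(moduleSizes) <- if (length(moduleSizes) == 6L) .MODULES else
        paste0("M", seq_along(moduleSizes))
    moduleOf <- rep.int(seq_along(moduleSizes), moduleSizes)
    labels <- sprintf("R%03d", seq_len(nRegions))
  }
  new("SynthConfig",
      nSubjects = as.integer(nSubjects), nRegions = nRegions,
      nTimepoints = as.integer(nTimepoints), trSeconds = trSeconds,
      moduleSizes = moduleSizes, moduleOf = as.integer(moduleOf),
      regionLabels = labels, withinCoupling = withinCoupling,
      betweenCoupling = betweenCoupling, hubCoupling = hubCoupling,
      hubBoost = hubBoost, bridgeCoupling = bridgeCoupling,
      bridgeBlockSize = as.integer(bridgeBlockSize),
      blockContrast = blockContrast, moduleContrast = moduleContrast,
      arCoefficient = arCoefficient, conditionEffect = conditionEffect,
      timeEffect = timeEffect, subjectSd = subjectSd,
      seed = as.integer(seed))
}

#' Designated hub regions of a configuration
#'
#' The planted hubs are, deterministically, the first region of each
#' module (lowest region index), avoiding any circularity with measured
#' centrality.
#'
#' @param config a [SynthConfig-class].
#' @return named integer vector of region indices, one per module.
#' @export
hubRegions <- function(config) {
  idx <- vapply(seq_along(config@moduleSizes),
                function(k) which(config@moduleOf == k)[1L], integer(1))
  setNames(idx, names(config@moduleSizes))
}

#' Connector-block layout of a configuration
#'
#' The session-rotating bridge structure is only defined for the
#' six-module design. Modules are ranked by size; each module
#' contributes one connector block (the regions immediately after its
#' hub, equal size across modules). Every connector is wired to exactly
#' three partner connectors in one other module, each wiring carried by
#' its own shared latent whose variance is chosen at generation time so
#' that every wired pair attains the same planted correlation
#' `bridgeCoupling`, whatever the baseline (floor) correlation of its
#' module pair; a connector's expected between-module degree is
#' therefore identical in every session and condition. What rotates across sessions is the *partner assignment*:
#' in the first session all wirings pair degree-similar modules (1st
#' with 2nd largest, 3rd with 4th, 5th with 6th); session by session a
#' growing fraction of connector slots (0, 1/3, 2/3, all) is rewired to
#' the degree-dissimilar pairing (1st with 6th, 2nd with 5th, 3rd with
#' 4th unchanged). Blocks in the two largest modules additionally carry
#' a positive loading contrast on their module-specific signal and
#' blocks in the two smallest a negative one, widening the degree
#' contrast that the rotation mixes while leaving between-module
#' baseline correlations untouched.
#'
#' @param config a [SynthConfig-class].
#' @return `NULL` when bridges are inactive, else a list with `blocks`
#'   (region indices per module), `earlyPairs`/`latePairs` (module index
#'   pairs), `contrast` (per-module loading delta on the module-specific
#'   signal), `blockSize`, and `wirings` (one two-column matrix of wired
#'   region pairs per session).
#' @export
connectorBlocks <- function(config) {
  nk <- length(config@moduleSizes)
  bs <- min(config@bridgeBlockSize, min(config@moduleSizes) - 1L)
  if (nk != 6L || config@bridgeCoupling <= 0 || bs < 3L) return(NULL)
  ord <- order(config@moduleSizes, decreasing = TRUE)
  blocks <- lapply(seq_len(nk), function(k)
    which(config@moduleOf == k)[2:(bs + 1L)])
  contrast <- numeric(nk)
  contrast[ord[1:2]] <- config@blockContrast
  contrast[ord[5:6]] <- -config@blockContrast
  earlyPairs <- list(ord[c(1L, 2L)], ord[c(3L, 4L)], ord[c(5L, 6L)])
  latePairs <- list(ord[c(1L, 6L)], ord[c(2L, 5L)], ord[c(3L, 4L)])
  wirings <- lapply(1:4, function(j) {
    t_s <- round(bs * (j - 1) / 3)         # slots already rewired
    rbind(
      do.call(rbind, lapply(earlyPairs, function(p)
        .wire_pair(blocks[[p[1L]]], blocks[[p[2L]]], p,
                   slots = seq_len(bs) > t_s))),
      do.call(rbind, lapply(latePairs, function(p)
        .wire_pair(blocks[[p[1L]]], blocks[[p[2L]]], p,
                   slots = seq_len(bs) <= t_s))))
  })
  list(blocks = blocks, earlyPairs = earlyPairs, latePairs = latePairs,
       contrast = contrast, blockSize = bs, wirings = wirings)
}

# wire the selected slots of two blocks: each selected connector of
# block A is paired with 3 cyclically-shifted selected connectors of
# block B (bipartite, so every connector gets exactly 3 partners);
# columns: region_a, region_b, module_a, module_b
.wire_pair <- function(blockA, blockB, modules, slots) {
  g <- sum(slots)
  if (g < 1L) return(NULL)
  a <- blockA[slots]; b <- blockB[slots]
  pairs <- do.call(rbind, lapply(0:2, function(o)
    cbind(a, b[1L + (seq_len(g) - 1L + o) %% g])))
  cbind(unique(pairs), modules[1L], modules[2L])
}

# stationary AR(1) series with unit marginal variance, one per column;
# the recursion runs over columns of the transposed matrix (contiguous
# memory), which matters because this is the generator's hot loop
.ar1_matrix <- function(nt, nc, phi) {
  if (phi == 0 || nt == 1L) return(matrix(rnorm(nt * nc), nt, nc))
  z <- matrix(rnorm(nt * nc) * sqrt(1 - phi^2), nc, nt)
  z[, 1L] <- z[, 1L] / sqrt(1 - phi^2)
  for (t in 2:nt) z[, t] <- z[, t] + phi * z[, t - 1L]
  t(z)
}

#' Generate a synthetic multi-subject cohort
#'
#' Draws the full factorial design: `nSubjects` x 2 conditions (RW, SR) x
#' 4 sessions (T1000, T1400, T1800, T2200), one
#' [SessionRecording-class] each, from the latent-signal model described
#' in [synthConfig()]. Per-subject coupling jitter is constant across a
#' subject's eight recordings (a within-subject design), and every
#' recording uses an RNG stream derived from the config seed, so
#' identical (config, seed) pairs reproduce byte-identical cohorts.
#'
#' @param config a [SynthConfig-class].
#' @return named list of `nSubjects * 8` [SessionRecording-class]
#'   objects, names `"<subject>_<condition>_<session>"`, ordered subject,
#'   then condition, then session.
#' @examples
#' cfg <- synthConfig(nSubjects = 2, nRegions = 24, nTimepoints = 100,
#'                    moduleSizes = rep(4L, 6), seed = 7)
#' cohort <- generateCohort(cfg)
#' length(cohort)   # 2 x 2 x 4 = 16
#' cohort[[1]]
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  nt <- config@nTimepoints
  nr <- config@nRegions
  nk <- length(config@moduleSizes)
  phi <- config@arCoefficient
  hubs <- hubRegions(config)
  is_hub <- seq_len(nr) %in% hubs
  module_of <- config@moduleOf

  # per-subject coupling jitter, one stream per subject
  subj_ids <- sprintf("S%02d", seq_len(config@nSubjects))
  jit <- lapply(seq_len(config@nSubjects), function(s) {
    set.seed(.derive_seed(config@seed, 100000 + s))
    {
      z <- rnorm(3)
      list(w = min(max(config@withinCoupling * (1 + config@subjectSd * z[1]),
                       0.01), 0.97),
           gamma = min(max(config@betweenCoupling *
                             (1 + config@subjectSd * z[2]), 0), 0.995),
           v = min(max(config@hubCoupling * (1 + config@subjectSd * z[3]),
                       0), 0.97))
    }
  })

  bridge <- connectorBlocks(config)
  psi <- if (is.null(bridge)) 0 else config@bridgeCoupling
  # static per-region delta on the module-specific loading; leaves the
  # shared-global loading (hence all between-module baselines) untouched
  contrast_of <- numeric(nr)
  if (!is.null(bridge))
    for (k in seq_len(nk))
      contrast_of[bridge$blocks[[k]]] <- bridge$contrast[k]

  # per-module within-coupling multiplier: the two largest modules are
  # more coherent, the two smallest less (only for six-module designs)
  mw <- rep(1, nk)
  if (nk == 6L && config@moduleContrast > 0) {
    ord <- order(config@moduleSizes, decreasing = TRUE)
    mw[ord[1:2]] <- 1 + config@moduleContrast
    mw[ord[5:6]] <- 1 - config@moduleContrast
  }

  out <- vector("list", config@nSubjects * 8L)
  nm <- character(length(out))
  idx <- 0L
  for (s in seq_len(config@nSubjects)) {
    w <- jit[[s]]$w
    e <- config@hubBoost
    v <- min(jit[[s]]$v, sqrt(max(0.98 - (w + e)^2, 0)))
    for (ci in 1:2) {
      cond <- .CONDITIONS[ci]
      gamma <- jit[[s]]$gamma * (1 - config@conditionEffect * (cond == "SR"))
      lg_mod <- w * mw * gamma              # per-module global loading
      lg <- lg_mod[module_of]               # per-region global loading
      lu0_mod <- w * mw * sqrt(1 - gamma^2) # per-module specific loading
      lu <- pmax(lu0_mod[module_of] + contrast_of, 0.02)
      for (j in 1:4) {
        idx <- idx + 1L
        decay <- 1 - config@timeEffect * (j - 1)   # hub attenuation
        vh <- v * decay
        lu_hub <- (lu0_mod + e) * decay            # per-module hub loading
        wiring <- if (is.null(bridge)) NULL else bridge$wirings[[j]]
        # per-wiring latent variance chosen so every wired pair reaches
        # the same planted correlation, whatever its floor product
        cpair <- if (is.null(wiring)) numeric(0) else
          pmax(psi - lg_mod[wiring[, 3L]] * lg_mod[wiring[, 4L]], 0.005)
        bvar <- numeric(nr)
        if (!is.null(wiring)) {
          for (p in seq_len(nrow(wiring))) {
            bvar[wiring[p, 1L]] <- bvar[wiring[p, 1L]] + cpair[p]
            bvar[wiring[p, 2L]] <- bvar[wiring[p, 2L]] + cpair[p]
          }
        }
        sig <- sqrt(pmax(1 - lg^2 - lu^2 - bvar, 0.02))
        rec_seed <- .derive_seed(config@seed, (s - 1L) * 8L +
                                   (ci - 1L) * 4L + j)
        set.seed(rec_seed)
        x <- {
          lat <- .ar1_matrix(nt, nk + 2L, phi)  # g, u_1..u_K, h
          g <- lat[, 1L]
          u <- lat[, 2:(nk + 1L), drop = FALSE]
          h <- lat[, nk + 2L]
          eps <- .ar1_matrix(nt, nr, phi)
          xx <- outer(g, lg) + u[, module_of, drop = FALSE] *
            rep(lu, each = nt) + eps * rep(sig, each = nt)
          if (!is.null(wiring)) {
            # one latent per wired connector pair
            bl <- .ar1_matrix(nt, nrow(wiring), phi)
            for (p in seq_len(nrow(wiring))) {
              term <- sqrt(cpair[p]) * bl[, p]
              xx[, wiring[p, 1L]] <- xx[, wiring[p, 1L]] + term
              xx[, wiring[p, 2L]] <- xx[, wiring[p, 2L]] + term
            }
          }
          # hubs: attenuated module loading plus the decaying shared
          # hub series (top-degree club in early sessions)
          for (k in seq_len(nk)) {
            hk <- hubs[k]
            s_h <- sqrt(max(1 - lg_mod[k]^2 - lu_hub[k]^2 - vh^2, 0.02))
            xx[, hk] <- lg_mod[k] * g + lu_hub[k] * u[, k] + vh * h +
              s_h * eps[, hk]
          }
          xx
        }
        colnames(x) <- config@regionLabels
        out[[idx]] <- new("SessionRecording", subjectId = subj_ids[s],
                          condition = cond, session = .SESSIONS[j],
                          data = x)
        nm[idx] <- paste(subj_ids[s], cond, .SESSIONS[j], sep = "_")
      }
    }
  }
  names(out) <- nm
  out
}

#' Write a cohort to disk as TSV recordings plus a manifest
#'
#' One tab-separated file per recording (rows = timepoints, columns =
#' region labels with a header row), a `manifest.csv` listing
#' `file, subject, condition, session`, and a copy of the node table when
#' one applies.
#'
#' @param cohort list of [SessionRecording-class] objects.
#' @param dir output directory, created if needed.
#' @param nodeTable optional node table to copy alongside the data.
#' @return the manifest data.frame, invisibly.
#' @export
writeCohort <- function(cohort, dir, nodeTable = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(rec) {
    fn <- paste0(rec@subjectId, "_", rec@condition, "_", rec@session, ".tsv")
    write.table(rec@data, file.path(dir, fn), sep = "\t", quote = FALSE,
                row.names = FALSE)
    data.frame(file = fn, subject = rec@subjectId,
               condition = rec@condition, session = rec@session,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE,
            quote = FALSE)
  if (!is.null(nodeTable))
    write.csv(nodeTable, file.path(dir, "node_table.csv"),
              row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read one recording from a TSV file
#'
#' @param file path to a timepoints-by-regions TSV with region labels as
#'   the header.
#' @param subject,condition,session the design factors of this recording.
#' @return a [SessionRecording-class].
#' @export
readRecording <- function(file, subject, condition, session) {
  x <- as.matrix(read.delim(file, check.names = FALSE))
  new("SessionRecording", subjectId = as.character(subject),
      condition = as.character(condition), session = as.character(session),
      data = x)
}

#' Read a cohort from a manifest
#'
#' Reads `manifest.csv` (columns `file, subject, condition, session`) and
#' loads every listed recording; checks the design is complete and
#' balanced (every subject has all 8 condition-by-session cells exactly
#' once) before reading any data.
#'
#' @param manifestPath path to the manifest CSV; recording paths are
#'   resolved relative to its directory.
#' @return named list of [SessionRecording-class] objects.
#' @export
readCohort <- function(manifestPath) {
  man <- read.csv(manifestPath, stringsAsFactors = FALSE)
  need <- c("file", "subject", "condition", "session")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  .check_design(man)
  base <- dirname(manifestPath)
  recs <- lapply(seq_len(nrow(man)), function(i)
    readRecording(file.path(base, man$file[i]), man$subject[i],
                  man$condition[i], man$session[i]))
  names(recs) <- paste(man$subject, man$condition, man$session, sep = "_")
  recs
}

# error before any computation if the 2 x 4 within-subject design is
# incomplete or duplicated, naming the offending cells
.check_design <- function(man) {
  cells <- expand.grid(condition = .CONDITIONS, session = .SESSIONS,
                       subject = unique(man$subject),
                       stringsAsFactors = FALSE)
  key <- function(d) paste(d$subject, d$condition, d$session, sep = "/")
  have <- key(man)
  if (anyDuplicated(have))
    stop("duplicated design cell(s): ",
         paste(unique(have[duplicated(have)]), collapse = ", "))
  missing <- setdiff(key(cells), have)
  if (length(missing))
    stop("incomplete design; missing cell(s): ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}
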