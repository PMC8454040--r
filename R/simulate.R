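#' Simulate a toy universe with class-clustered reactions and planted pathways
#'
#' Generates the study conditions for desk-scale experiments: a seeded
#' [ToyChemistry-class] universe, a registered-reaction table whose
#' reaction-feature vectors cluster by synthetic EC class, and planted
#' start/target queries that are exactly solvable by known registered
#' reaction sequences.
#'
#' Each synthetic 3-digit EC class is a base fragment-count change (its
#' entries scale with `classSeparation`); individual reactions of the class
#' apply the base change plus small integer within-class noise to a random
#' substrate, and the resulting product is added to the universe. Classes
#' pair up under shared 2-digit prefixes so confusion-matrix aggregation is
#' exercised. Because the toy embedding is linear, a planted pathway's
#' reaction vectors sum exactly to its query's pathway-feature vector
#' (residual `|e| = 0`) and every segment's molecular-weight change equals
#' the registered change exactly.
#'
#' @param nCompounds number of seed compounds drawn before reaction products
#'   are added (the final universe is somewhat larger).
#' @param nReactions number of registered reactions.
#' @param nEcClasses number of synthetic 3-digit EC classes.
#' @param nFragments,latentDim toy-chemistry sizes (see [makeToyUniverse()]).
#' @param classSeparation magnitude of the class base changes, in fragment
#'   counts; 0 removes the between-class signal entirely so classification
#'   falls to chance.
#' @param withinNoise maximum per-coordinate within-class perturbation.
#' @param plantedLengths integer vector of planted pathway lengths (in
#'   reaction steps); one query is planted per entry.
#' @param seed master seed; the whole scenario is reproducible from it.
#' @return list with `backend` (a [ToyChemistry-class]), `records`
#'   (reaction table data.frame), and `manifest`: one entry per planted
#'   query with `startId`, `targetId`, `ec` (the planted EC sequence) and
#'   `recordRows` (row indices of the planted reactions in `records`).
#' @export
simulateUniverse <- function(nCompounds = 120L, nReactions = 240L,
                             nEcClasses = 6L, nFragments = 8L,
                             latentDim = 8L, classSeparation = 4L,
                             withinNoise = 1L, plantedLengths = c(1L, 2L),
                             seed = 1L) {
  if (nEcClasses < 2L) stopParam("need at least 2 EC classes")
  if (classSeparation < 0L) stopParam("classSeparation must be >= 0")
  withSeed(seed, {
    masses <- round(stats::runif(nFragments, 12, 60), 2)
    mixing <- randomFullRank(latentDim, nFragments)

    # distinct integer base changes per class, magnitude ~ classSeparation
    bases <- matrix(0L, nEcClasses, nFragments)
    if (classSeparation > 0L) {
      taken <- character(0)
      for (c in seq_len(nEcClasses)) {
        repeat {
          b <- integer(nFragments)
          coords <- sample.int(nFragments, min(3L, nFragments))
          b[coords] <- sample(c(-classSeparation:-1, 1:classSeparation),
                              length(coords), replace = TRUE)
          key <- paste(b, collapse = ",")
          if (!key %in% taken) { taken <- c(taken, key); bases[c, ] <- b; break }
        }
      }
    }

    # seed compounds: sparse fragment compositions (a compound contains a few
    # fragment types, not all), so valid compounds occupy a thin region of
    # latent space and random vector arithmetic tends to leave it - the toy
    # analogue of latent points that decode to no realistic structure
    counts <- matrix(0L, 0L, nFragments)
    while (nrow(counts) < nCompounds) {
      cand <- integer(nFragments)
      active <- sample.int(nFragments, sample(2:4, 1L))
      cand[active] <- sample.int(6L, length(active), replace = TRUE)
      counts <- unique(rbind(counts, cand))
    }

    addCompound <- function(cnt) {
      hit <- which(apply(counts, 1L, function(r) all(r == cnt)))
      if (length(hit)) return(hit[1L])
      counts <<- rbind(counts, as.integer(cnt))
      nrow(counts)
    }

    ecOf <- function(c) sprintf("%d.%d.%d", (c - 1L) %/% 2L + 1L,
                                (c - 1L) %% 2L + 1L, c)

    noiseVec <- function() {
      nz <- integer(nFragments)
      if (withinNoise > 0L) {
        coords <- sample.int(nFragments, 2L)
        nz[coords] <- sample(-withinNoise:withinNoise, 2L, replace = TRUE)
      }
      nz
    }

    subRow <- integer(nReactions); prodRow <- integer(nReactions)
    ec <- character(nReactions)
    for (i in seq_len(nReactions)) {
      cls <- (i - 1L) %% nEcClasses + 1L
      repeat {
        s <- sample.int(nCompounds, 1L)
        delta <- bases[cls, ] + noiseVec()
        prod <- counts[s, ] + delta
        if (all(prod >= 0L) && !all(delta == 0L) &&
            !all(prod == counts[s, ])) break
      }
      subRow[i] <- s
      prodRow[i] <- addCompound(prod)
      ec[i] <- paste0(ecOf(cls), ".", i)
    }

    # planted queries: chains of registered reactions applied from a fresh start
    manifest <- list()
    for (L in plantedLengths) {
      repeat {
        rows <- sample.int(nReactions, L)
        start <- counts[sample.int(nCompounds, 1L), ]
        nodes <- list(start)
        ok <- TRUE
        for (k in seq_len(L)) {
          delta <- counts[prodRow[rows[k]], ] - counts[subRow[rows[k]], ]
          nxt <- nodes[[k]] + delta
          if (any(nxt < 0L)) { ok <- FALSE; break }
          nodes[[k + 1L]] <- nxt
        }
        if (!ok) next
        if (all(nodes[[L + 1L]] == nodes[[1L]])) next
        nodeRows <- vapply(nodes, addCompound, integer(1))
        manifest[[length(manifest) + 1L]] <-
          list(length = L, startRow = nodeRows[1L],
               targetRow = nodeRows[L + 1L], recordRows = rows,
               ec = ec[rows])
        break
      }
    }

    ids <- sprintf("T%05d", seq_len(nrow(counts)))
    rownames(counts) <- ids
    backend <- methods::new("ToyChemistry", name = "toy",
                            fragmentMasses = masses, mixingMatrix = mixing,
                            graphMixing = mixing, counts = counts,
                            seed = as.integer(seed))
    records <- data.frame(ec_number = ec,
                          substrate_id = ids[subRow],
                          product_id = ids[prodRow],
                          stringsAsFactors = FALSE)
    manifest <- lapply(manifest, function(m)
      list(length = m$length, startId = ids[m$startRow],
           targetId = ids[m$targetRow], ec = m$ec,
           recordRows = m$recordRows))
    list(backend = backend, records = records, manifest = manifest)
  })
}

#' Run the full exploration pipeline: design then score
#'
#' Builds (or accepts) the reaction-feature DB, designs candidate pathways
#' for the query with [designCandidates()], scores every kept candidate with
#' the ensemble, and returns them sorted ascending by score `s` (ties broken
#' by higher feasibility `vP`). An empty candidate list is a valid outcome.
#'
#' @param backend a decoding-capable [EmbeddingBackend-class].
#' @param records registered-reaction data.frame (see [readReactionTable()]).
#' @param startId,targetId the query compounds.
#' @param cfg a [deConfig()] list.
#' @param model an [EnsembleModel-class] used for scoring; when `NULL` the
#'   candidates are returned designed but unscored (ranked by `|e|`).
#' @param db optional prebuilt tree-part [ReactionFeatureDB-class]; built
#'   from `records` otherwise.
#' @param scoreForm passed to [scorePathway()].
#' @return list with `candidates` (sorted list of [CandidatePathway-class]),
#'   `report` (one row per candidate: EC sequence, `absError`, `vP`, `s`),
#'   and `log` from the design stage.
#' @export
explore <- function(backend, records, startId, targetId, cfg,
                    model = NULL, db = NULL,
                    scoreForm = c("ratio", "product")) {
  scoreForm <- match.arg(scoreForm)
  if (is.null(db)) db <- buildReactionDB(records, backend, part = "tree")
  query <- pathwayQuery(backend, startId, targetId, part = db@part)
  cands <- designCandidates(query, db, cfg, backend)
  log <- attr(cands, "log")
  if (!is.null(model))
    cands <- lapply(cands, scorePathway, model = model, backend = backend,
                    scoreForm = scoreForm)
  if (length(cands)) {
    s <- vapply(cands, function(p)
      if (is.na(p@score)) p@absError else p@score, numeric(1))
    vp <- vapply(cands, function(p)
      if (is.na(p@vP)) 0 else p@vP, numeric(1))
    ord <- order(s, -vp)
    cands <- cands[ord]
  }
  report <- if (length(cands)) do.call(rbind, lapply(cands, function(p)
    data.frame(ec = paste(p@ec, collapse = ">"),
               steps = length(p@ec),
               absError = p@absError, vP = p@vP, s = p@score,
               stringsAsFactors = FALSE)))
  else data.frame(ec = character(), steps = integer(),
                  absError = numeric(), vP = numeric(), s = numeric())
  list(candidates = cands, report = report, log = log)
}
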