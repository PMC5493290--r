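#' Grow native cell areas and advance ages
#'
#' Constant-rate compounding growth of the native (target) area,
#' \eqn{A_0(t + dt) = (1 + \eta\,dt)\,A_0(t)}, applied to every interior
#' cell; ages advance by dt.
#'
#' @param tissue a [Tissue-class] object.
#' @param eta growth rate (1/time).
#' @param dt time step.
#' @return the updated tissue.
#' @export
growCells <- function(tissue, eta, dt) {
  stopifnot(dt > 0)
  interior <- isInterior(tissue)
  tissue@A0[interior] <- tissue@A0[interior] * (1 + eta * dt)
  tissue@age[interior] <- tissue@age[interior] + dt
  tissue
}

#' Division probability over a check interval
#'
#' A cell with actual area A above the critical area divides with rate
#' \eqn{\chi (A - A_c)} (zero otherwise).  Over a check interval of length
#' `interval` the probability is min(rate * interval, 1), so the division
#' law does not depend on the simulation time step.
#'
#' @param area actual cell area(s).
#' @param pop a [PopulationParams-class] object.
#' @param interval elapsed time covered by this check (> 0).
#' @return probability vector.
#' @export
divisionProbability <- function(area, pop, interval) {
  stopifnot(interval > 0)
  pmin(pop@chi * pmax(area - pop@Ac, 0) * interval, 1)
}

#' Divide a cell into two daughters
#'
#' The mother is replaced by two daughters placed at
#' \eqn{r \pm (\mathrm{offset}/2)\, n} along the mother's polarity vector;
#' both daughters start with age zero and half the mother's native area and
#' inherit her polarity and type.  The triangulation is rebuilt.
#'
#' @param tissue a [Tissue-class] object.
#' @param cell row index of the mother (must be interior).
#' @param pop a [PopulationParams-class] object.
#' @param rebuild logical: rebuild the Delaunay mesh now (default TRUE; set
#'   FALSE when batching several divisions).
#' @return list(tissue, event): the grown tissue (one extra row, appended
#'   daughter) and a one-row event data.frame.
#' @export
divideCell <- function(tissue, cell, pop, rebuild = TRUE) {
  if (tissue@flag[cell] != "interior") stop("only interior cells divide")
  nvec <- c(cos(tissue@theta[cell]), sin(tissue@theta[cell]))
  r0 <- tissue@pos[cell, ]
  off <- pop@daughterOffset / 2
  p1 <- r0 + off * nvec
  p2 <- r0 - off * nvec
  # collision guard: jitter if a daughter lands on an existing particle
  for (pp in list(p1, p2)) {
    d2 <- rowSums((tissue@pos - matrix(pp, nrow(tissue@pos), 2, byrow = TRUE))^2)
    d2[cell] <- Inf
    if (min(d2) < 1e-12) {
      warning("daughter placement collides with an existing site; jittering")
      p1 <- p1 + c(1e-4, 0); p2 <- p2 - c(1e-4, 0)
    }
  }
  motherId <- tissue@id[cell]
  newId <- max(tissue@id) + 1L
  halfA0 <- tissue@A0[cell] / 2
  tissue@pos[cell, ] <- p1
  tissue@A0[cell] <- halfA0
  tissue@age[cell] <- 0
  tissue@id[cell] <- newId
  tissue@pos <- rbind(tissue@pos, p2)
  rownames(tissue@pos) <- NULL
  tissue@flag <- c(tissue@flag, "interior")
  tissue@type <- c(tissue@type, tissue@type[cell])
  tissue@theta <- c(tissue@theta, tissue@theta[cell])
  tissue@A0 <- c(tissue@A0, halfA0)
  tissue@age <- c(tissue@age, 0)
  tissue@id <- c(tissue@id, newId + 1L)
  tissue@bnext <- c(tissue@bnext, 0L)
  tissue@bprev <- c(tissue@bprev, 0L)
  tissue@stale <- TRUE
  if (rebuild) tissue <- buildTriangulation(tissue)
  list(tissue = tissue,
       event = data.frame(event = "division", id1 = motherId, id2 = newId,
                          id3 = newId + 1L, id4 = NA_integer_))
}

#' Remove a cell from the tissue
#'
#' The particle is deleted instantaneously and the triangulation rebuilt;
#' neighbouring cells enlarge to tile the vacated area.
#'
#' @param tissue a [Tissue-class] object.
#' @param cell row index of the cell to remove (interior).
#' @param rebuild logical; rebuild the mesh now (default TRUE).
#' @return list(tissue, event).
#' @export
removeCell <- function(tissue, cell, rebuild = TRUE) {
  if (tissue@flag[cell] != "interior") stop("only interior cells can be removed")
  if (nCells(tissue) <= 1L)
    stop("cannot remove the last interior cell")
  deadId <- tissue@id[cell]
  keep <- setdiff(seq_len(nrow(tissue@pos)), cell)
  remap <- integer(nrow(tissue@pos)); remap[keep] <- seq_along(keep)
  tissue@pos <- tissue@pos[keep, , drop = FALSE]
  tissue@flag <- tissue@flag[keep]; tissue@type <- tissue@type[keep]
  tissue@theta <- tissue@theta[keep]; tissue@A0 <- tissue@A0[keep]
  tissue@age <- tissue@age[keep]; tissue@id <- tissue@id[keep]
  tissue@bnext <- remapLinks(tissue@bnext[keep], remap)
  tissue@bprev <- remapLinks(tissue@bprev[keep], remap)
  tissue@stale <- TRUE
  if (rebuild) tissue <- buildTriangulation(tissue)
  list(tissue = tissue,
       event = data.frame(event = "death", id1 = deadId, id2 = NA_integer_,
                          id3 = NA_integer_, id4 = NA_integer_))
}

# division / death sweep used by runSimulation; interval is the elapsed time
# since the previous check
populationSweep <- function(tissue, pop, interval, areas = NULL) {
  events <- list()
  if (pop@enableDeath && is.finite(pop@maxAge)) {
    repeat {
      old <- which(isInterior(tissue) & tissue@age >= pop@maxAge)
      if (!length(old)) break
      r <- removeCell(tissue, old[1], rebuild = FALSE)
      tissue <- r$tissue
      events[[length(events) + 1L]] <- r$event
      areas <- NULL  # indices shifted; recompute below if needed
    }
  }
  if (pop@chi > 0) {
    if (is.null(areas)) {
      if (tissue@stale) tissue <- buildTriangulation(tissue)
      g <- cpp_cell_geometry(tissue@pos, tissue@triangles, isInterior(tissue))
      areas <- setNames(g$area, g$site)
    }
    sites <- as.integer(names(areas))
    p <- divisionProbability(areas, pop, interval)
    divide <- sites[runif(length(p)) < p]
    for (cell in divide) {
      r <- divideCell(tissue, cell, pop, rebuild = FALSE)
      tissue <- r$tissue
      events[[length(events) + 1L]] <- r$event
    }
  }
  if (tissue@stale) tissue <- buildTriangulation(tissue)
  list(tissue = tissue,
       events = if (length(events)) do.call(rbind, events) else NULL)
}
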