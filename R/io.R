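# Snapshot format: two delimited text tables.
#   <prefix>.sites.tsv  - one row per particle: id flag type x y theta A0 age
#   <prefix>.bonds.tsv  - boundary connectivity: id left right (stable ids)
# The mesh itself is never serialised; it is rebuilt from the sites.

fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

tissueFrame <- function(tissue) {
  data.frame(id = tissue@id, flag = tissue@flag, type = tissue@type,
             x = tissue@pos[, 1], y = tissue@pos[, 2],
             theta = tissue@theta, A0 = tissue@A0, age = tissue@age,
             stringsAsFactors = FALSE)
}

#' Write a tissue snapshot to delimited text
#'
#' @param tissue a [Tissue-class] object.
#' @param prefix file prefix; `<prefix>.sites.tsv` and `<prefix>.bonds.tsv`
#'   are (over)written.
#' @return invisibly, the two file names.
#' @export
writeSnapshot <- function(tissue, prefix) {
  df <- tissueFrame(tissue)
  for (cc in c("x", "y", "theta", "A0", "age")) df[[cc]] <- fmt(df[[cc]])
  sitesFile <- paste0(prefix, ".sites.tsv")
  bondsFile <- paste0(prefix, ".bonds.tsv")
  write.table(df, sitesFile, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- which(tissue@flag != "interior")
  bonds <- data.frame(id = tissue@id[g],
                      left = tissue@id[tissue@bprev[g]],
                      right = tissue@id[tissue@bnext[g]])
  write.table(bonds, bondsFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(sitesFile, bondsFile))
}

#' Read a tissue snapshot written by [writeSnapshot()]
#'
#' @param prefix file prefix.
#' @param build rebuild the Delaunay mesh (default TRUE).
#' @return a [Tissue-class] object.
#' @export
readSnapshot <- function(prefix, build = TRUE) {
  df <- read.table(paste0(prefix, ".sites.tsv"), header = TRUE, sep = "\t",
                   colClasses = c(id = "integer", flag = "character",
                                  type = "character", x = "numeric",
                                  y = "numeric", theta = "numeric",
                                  A0 = "numeric", age = "numeric"))
  bonds <- read.table(paste0(prefix, ".bonds.tsv"), header = TRUE, sep = "\t")
  n <- nrow(df)
  bnext <- bprev <- integer(n)
  if (nrow(bonds)) {
    row <- match(bonds$id, df$id)
    bnext[row] <- match(bonds$right, df$id)
    bprev[row] <- match(bonds$left, df$id)
  }
  tis <- new("Tissue", pos = cbind(x = df$x, y = df$y), flag = df$flag,
             type = df$type, theta = df$theta, A0 = df$A0, age = df$age,
             id = df$id, bnext = bnext, bprev = bprev,
             triangles = matrix(integer(), 0, 3), stale = TRUE)
  validObject(tis)
  if (build) tis <- buildTriangulation(tis)
  tis
}

paramsToList <- function(p) {
  out <- lapply(slotNames(class(p)), function(s) {
    v <- slot(p, s)
    if (is.matrix(v)) {
      l <- as.list(as.data.frame(v))
      attr(l, "rownames") <- rownames(v)
      l
    } else v
  })
  names(out) <- slotNames(class(p))
  out
}

#' Write the run manifest
#'
#' A YAML dump of every parameter object, the seed(s) and the RNG state,
#' sufficient to re-run the simulation bit-identically.
#'
#' @param file output path.
#' @param ... named parameter objects / values to record.
#' @export
writeManifest <- function(file, ...) {
  args <- list(...)
  ser <- lapply(args, function(a) {
    if (is(a, "Tissue")) return(list(n_particles = nrow(a@pos)))
    if (isS4(a)) paramsToList(a) else a
  })
  ser$rng_state <- if (exists(".Random.seed", globalenv()))
    as.integer(get(".Random.seed", globalenv())) else NULL
  ser$package_version <- as.character(utils::packageVersion("avm"))
  yaml::write_yaml(ser, file)
  invisible(file)
}

#' Read a simulation configuration file
#'
#' Flat YAML with sections `scenario`, `mech`, `active`, `population`,
#' `boundary`, `run`; every key maps to the corresponding constructor
#' argument.  `mech$Lambda` may be a scalar (uniform tension), or a map of
#' type-pair keys such as `r.r: -6.8`, `r.b: -6.4`, `r.M: -6.2` (symmetric
#' completion is automatic).
#'
#' @param file path to a YAML config.
#' @return list(scenario, mech, active, population, boundary, run) of
#'   parameter objects / lists.
#' @export
readConfig <- function(file) {
  cfg <- yaml::read_yaml(file)
  sc <- cfg$scenario %||% list()
  types <- names(sc$typeFractions %||% c(c = 1))
  mechArgs <- cfg$mech %||% list()
  if (!is.null(mechArgs$Lambda) && is.list(mechArgs$Lambda)) {
    all_t <- c(types, "M")
    L <- matrix(NA_real_, length(all_t), length(all_t),
                dimnames = list(all_t, all_t))
    for (key in names(mechArgs$Lambda)) {
      pair <- strsplit(key, ".", fixed = TRUE)[[1]]
      L[pair[1], pair[2]] <- L[pair[2], pair[1]] <- mechArgs$Lambda[[key]]
    }
    if (anyNA(L)) stop("incomplete Lambda matrix in config")
    mechArgs$Lambda <- L
  }
  mechArgs$types <- types
  list(scenario = sc,
       mech = do.call(MechParams, mechArgs),
       active = do.call(ActiveParams, cfg$active %||% list()),
       population = do.call(PopulationParams, cfg$population %||% list()),
       boundary = do.call(BoundaryParams, cfg$boundary %||% list()),
       run = cfg$run %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trajectory to a directory
#'
#' Frames as numbered snapshot pairs plus `events.tsv` and
#' `boundary_length.tsv`.
#'
#' @param traj a [Trajectory-class] object.
#' @param dir output directory (created).
#' @export
writeTrajectory <- function(traj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(traj@frames)) {
    f <- traj@frames[[k]]
    out <- f
    for (cc in c("x", "y", "theta", "A0", "age")) out[[cc]] <- fmt(out[[cc]])
    write.table(out, file.path(dir, sprintf("frame_%06d.tsv", k)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(data.frame(time = traj@times),
              file.path(dir, "times.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(traj@events, file.path(dir, "events.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(time = traj@stepTimes, length = traj@boundaryLength),
              file.path(dir, "boundary_length.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeSnapshot(traj@finalTissue, file.path(dir, "final"))
  invisible(dir)
}
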