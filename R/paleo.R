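#' Construct a paleo-structure (epochs, areas, biomes, adjacency)
#'
#' A paleo-structure describes how the world available to a clade changed
#' through time: a set of geological epochs tiling time back from the
#' present, a list of geographic areas with a per-epoch symmetric adjacency
#' matrix (`geo_adjacency`), and a list of biomes with a per-epoch
#' area-by-biome availability matrix (`biome_availability`).  Matrix
#' entries take values in `{0, weak_value, 1}`: absent, weakly connected /
#' marginally available, or strongly connected / widespread.
#'
#' Epochs must tile `[0, Inf)` looking backward with no gaps or overlaps;
#' ages older than the oldest epoch's start are assigned to the oldest
#' epoch.  Intervals are half-open `[end, start)`.
#'
#' @param epochs data.frame with columns `name`, `start`, `end` (Ma before
#'   present, `start` older than `end`); the youngest epoch must end at 0.
#' @param areas character vector of area names.
#' @param biomes character vector of biome names.
#' @param geo_adjacency list (one per epoch) of area x area matrices.
#' @param biome_availability list (one per epoch) of area x biome matrices.
#' @param weak_value scalar in (0, 1) used for "weak" connectivity
#'   (default 0.1).
#' @return an object of class `"paleo_structure"`.
#' @export
paleo_structure <- function(epochs, areas, biomes, geo_adjacency,
                            biome_availability, weak_value = 0.1) {
  epochs <- as.data.frame(epochs)
  if (!all(c("name", "start", "end") %in% names(epochs)))
    stop("'epochs' needs columns name, start, end")
  if (!(is.numeric(weak_value) && length(weak_value) == 1 &&
        weak_value > 0 && weak_value < 1))
    stop("'weak_value' must be a scalar in (0, 1)")
  o <- order(epochs$start, decreasing = TRUE)
  epochs <- epochs[o, , drop = FALSE]
  rownames(epochs) <- NULL
  K <- nrow(epochs)
  if (any(epochs$start <= epochs$end))
    stop("each epoch must have start (older) > end (younger)")
  if (abs(epochs$end[K]) > 1e-9)
    stop("youngest epoch must end at the present (end = 0)")
  if (K > 1) {
    for (i in seq_len(K - 1)) {
      d <- epochs$end[i] - epochs$start[i + 1]
      if (abs(d) > 1e-9)
        stop(sprintf("epochs do not tile time: %s %g-%g between '%s' and '%s'",
                     if (d > 0) "gap" else "overlap",
                     min(epochs$end[i], epochs$start[i + 1]),
                     max(epochs$end[i], epochs$start[i + 1]),
                     epochs$name[i], epochs$name[i + 1]))
    }
  }
  areas <- as.character(areas); biomes <- as.character(biomes)
  if (anyDuplicated(areas) || anyDuplicated(biomes))
    stop("area and biome names must be unique")
  nA <- length(areas); nB <- length(biomes)
  geo_adjacency <- .paleo_matrices(geo_adjacency, K, nA, nA, areas, areas,
                                   weak_value, "geo_adjacency")
  biome_availability <- .paleo_matrices(biome_availability, K, nA, nB, areas,
                                        biomes, weak_value,
                                        "biome_availability")
  for (k in seq_len(K)) {
    G <- geo_adjacency[[k]]
    if (max(abs(G - t(G))) > 1e-12)
      stop(sprintf("geo_adjacency for epoch '%s' is not symmetric",
                   epochs$name[k]))
  }
  structure(list(epochs = epochs, areas = areas, biomes = biomes,
                 geo_adjacency = geo_adjacency,
                 biome_availability = biome_availability,
                 weak_value = weak_value),
            class = "paleo_structure")
}

# Coerce, name and validate a per-epoch list of matrices; entries may use
# the string "weak" in place of the numeric weak value.
.paleo_matrices <- function(ml, K, nr, nc, rn, cn, weak_value, what) {
  if (length(ml) != K)
    stop(sprintf("'%s' must have one matrix per epoch (%d)", what, K))
  lapply(ml, function(M) {
    if (is.list(M)) M <- do.call(rbind, lapply(M, unlist))
    if (is.character(M)) {
      M[M == "weak"] <- weak_value
      storage.mode(M) <- "double"
    }
    M <- as.matrix(M)
    storage.mode(M) <- "double"
    if (!all(dim(M) == c(nr, nc)))
      stop(sprintf("'%s' matrices must be %d x %d", what, nr, nc))
    ok <- abs(M) < 1e-12 | abs(M - 1) < 1e-12 | abs(M - weak_value) < 1e-12
    if (!all(ok))
      stop(sprintf("'%s' entries must be in {0, %g, 1}; found %s", what,
                   weak_value,
                   paste(unique(signif(M[!ok], 6)), collapse = ", ")))
    dimnames(M) <- list(rn, cn)
    M
  })
}

#' Load a paleo-structure from a YAML or JSON config
#'
#' The config carries keys `epochs` (list of `name`/`start`/`end`),
#' `areas`, `biomes`, `geo_adjacency`, `biome_availability` and optionally
#' `weak_value`.  Matrix entries may be numeric or the string `"weak"`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [paleo_structure()].
#' @export
load_paleo_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  else stop("config must be .yaml/.yml or .json: ", path)
  need <- c("epochs", "areas", "biomes", "geo_adjacency", "biome_availability")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("config missing key(s): ", paste(miss, collapse = ", "))
  ep <- cfg$epochs
  if (is.list(ep) && !is.data.frame(ep))
    ep <- do.call(rbind, lapply(ep, function(e)
      data.frame(name = e$name, start = as.numeric(e$start),
                 end = as.numeric(e$end))))
  paleo_structure(ep, cfg$areas, cfg$biomes, cfg$geo_adjacency,
                  cfg$biome_availability,
                  weak_value = cfg$weak_value %||% 0.1)
}

#' The bundled rock-daisy ("perityleae") paleo-structure preset
#'
#' Four areas (South America, Baja California, Trans-Mexican Volcanic
#' Belt, Basin and Range Province), four biomes (tropical, temperate,
#' subtropical, desert) and four epochs: Oligocene (33.9-23.0 Ma), early
#' Miocene (23.0-16 Ma), mid/late Miocene (16-5.3 Ma) and recent (5.3-0
#' Ma).  South America has zero connectivity to all other areas in every
#' epoch (its occupation is reachable only through the uninformed rate
#' component, representing rare long-distance dispersal).  Baja California
#' is strongly connected to the two mainland areas through the Oligocene
#' and early Miocene, weakly in the mid/late Miocene and disconnected in
#' the recent epoch (peninsular rifting).  Tropical, temperate and
#' subtropical biomes are available everywhere in all epochs; the desert
#' biome is absent before the mid/late Miocene, weakly available in the
#' mid/late Miocene and widespread in the recent epoch.
#'
#' @param weak_value scalar in (0,1) used for weak connectivity
#'   (default 0.1).
#' @return a [paleo_structure()].
#' @export
paleo_perityleae <- function(weak_value = 0.1) {
  areas <- c("SouthAmerica", "BajaCalifornia", "TransMexVolcanicBelt",
             "BasinAndRange")
  biomes <- c("tropical", "temperate", "subtropical", "desert")
  epochs <- data.frame(
    name = c("Oligocene", "earlyMiocene", "midLateMiocene", "recent"),
    start = c(33.9, 23.0, 16.0, 5.3),
    end = c(23.0, 16.0, 5.3, 0.0))
  baja <- c(1, 1, weak_value, 0)      # Baja <-> mainland, per epoch
  desert <- c(0, 0, weak_value, 1)    # desert availability, per epoch
  G <- lapply(1:4, function(k) {
    M <- matrix(0, 4, 4, dimnames = list(areas, areas))
    diag(M) <- 1
    M["TransMexVolcanicBelt", "BasinAndRange"] <- 1
    M["BasinAndRange", "TransMexVolcanicBelt"] <- 1
    M["BajaCalifornia", c("TransMexVolcanicBelt", "BasinAndRange")] <- baja[k]
    M[c("TransMexVolcanicBelt", "BasinAndRange"), "BajaCalifornia"] <- baja[k]
    M
  })
  B <- lapply(1:4, function(k) {
    M <- matrix(1, 4, 4, dimnames = list(areas, biomes))
    M[, "desert"] <- desert[k]
    M
  })
  paleo_structure(epochs, areas, biomes, G, B, weak_value = weak_value)
}

#' Epoch index containing a given age
#'
#' Intervals are half-open `[end, start)` looking backward; ages at or
#' beyond the oldest start belong to the oldest epoch.
#'
#' @param paleo a `paleo_structure`, or a numeric vector of epoch start
#'   ages in decreasing order (oldest first) whose implied ends follow by
#'   tiling down to 0.
#' @param age numeric vector of ages (Ma).
#' @return integer vector of epoch indices (1 = oldest).
#' @export
epoch_index <- function(paleo, age) {
  starts <- if (inherits(paleo, "paleo_structure")) paleo$epochs$start
            else sort(as.numeric(paleo), decreasing = TRUE)
  if (any(age < 0)) stop("ages must be >= 0")
  K <- length(starts)
  # epoch k covers [start_{k+1}, start_k); epoch K covers [0, start_K)
  idx <- K + 1L - findInterval(age, rev(c(starts[-1], 0)), left.open = FALSE)
  idx[age >= starts[1]] <- 1L
  pmin(pmax(idx, 1L), K)
}

#' @export
print.paleo_structure <- function(x, ...) {
  cat(sprintf(
    "Paleo-structure: %d epochs (%g-0 Ma), %d areas, %d biomes, weak = %g\n",
    nrow(x$epochs), max(x$epochs$start), length(x$areas), length(x$biomes),
    x$weak_value))
  print(x$epochs)
  invisible(x)
}

# Interior epoch boundaries (ages), oldest first; empty for 1 epoch.
.epoch_bounds <- function(paleo) {
  K <- nrow(paleo$epochs)
  if (K <= 1) numeric(0) else paleo$epochs$end[seq_len(K - 1)]
}
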