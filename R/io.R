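# Track and snapshot persistence. Tracks are plain CSV; snapshots are a
# versioned plain-text format that round-trips every double bit-exactly
# (printed with 17 significant digits) including the RNG stream states, so a
# resumed run reproduces an uninterrupted one.

.SNAPSHOT_VERSION <- 1L

#' Write a track table to CSV
#'
#' @param track data.frame from a [simulateCell()] run (`run$track`).
#' @param path output file.
#' @export
writeTrack <- function(track, path) {
  write.csv(track, path, row.names = FALSE)
  invisible(path)
}

#' Read a track table from CSV
#'
#' @param path file written by [writeTrack()].
#' @return data.frame.
#' @export
readTrack <- function(path) {
  tr <- read.csv(path)
  # an all-NA numeric column (e.g. energy when not recorded) parses as
  # logical; restore its numeric type
  for (j in seq_along(tr))
    if (is.logical(tr[[j]]) && all(is.na(tr[[j]]))) tr[[j]] <- as.numeric(tr[[j]])
  tr
}

.fmt <- function(x) sprintf("%.17g", x)

#' Write a snapshot of the full simulation state
#'
#' @param st a `cellState`.
#' @param path output file (plain text).
#' @export
writeSnapshot <- function(st, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste(...), con)
  w("mtmigrate-snapshot", .SNAPSHOT_VERSION)
  w("t", .fmt(st$t))
  w("rng_mt", st$rng_mt)
  w("rng_motor", st$rng_motor)
  w("centrosome", .fmt(st$centrosome[1]), .fmt(st$centrosome[2]))
  w("membrane", nrow(st$membrane))
  writeLines(paste(.fmt(st$membrane[, 1]), .fmt(st$membrane[, 2])), con)
  w("nucleus", nrow(st$nucleus))
  writeLines(paste(.fmt(st$nucleus[, 1]), .fmt(st$nucleus[, 2])), con)
  w("mts", length(st$mts))
  for (mt in st$mts) {
    w("mt", nrow(mt$beads), mt$state, .fmt(mt$partial), .fmt(mt$dir),
      as.integer(isTRUE(mt$dep_armed)))
    writeLines(paste(.fmt(mt$beads[, 1]), .fmt(mt$beads[, 2])), con)
  }
  w("ctrace", length(st$contract_trace))
  if (length(st$contract_trace))
    writeLines(.fmt(st$contract_trace), con)
  w("motors", nrow(st$motors))
  if (nrow(st$motors))
    writeLines(paste(st$motors$loop, st$motors$bead,
                     as.integer(st$motors$bound),
                     ifelse(is.na(st$motors$mt), -1L, st$motors$mt),
                     .fmt(st$motors$arc)), con)
  invisible(path)
}

#' Read a snapshot written by [writeSnapshot()]
#'
#' @param path snapshot file.
#' @return a `cellState`.
#' @export
readSnapshot <- function(path) {
  lines <- readLines(path)
  i <- 1L
  nxt <- function() {
    if (i > length(lines)) stop("truncated snapshot file: ", path)
    ln <- lines[[i]]
    i <<- i + 1L
    strsplit(ln, " ", fixed = TRUE)[[1]]
  }
  hd <- nxt()
  if (hd[1] != "mtmigrate-snapshot")
    stop("not a snapshot file: ", path)
  if (as.integer(hd[2]) != .SNAPSHOT_VERSION)
    stop("snapshot schema version ", hd[2], " not supported (expected ",
         .SNAPSHOT_VERSION, ")")
  fields <- list()
  tln <- nxt(); stopifnot(tln[1] == "t"); fields$t <- as.numeric(tln[2])
  r1 <- nxt(); stopifnot(r1[1] == "rng_mt")
  fields$rng_mt <- paste(r1[-1], collapse = " ")
  r2 <- nxt(); stopifnot(r2[1] == "rng_motor")
  fields$rng_motor <- paste(r2[-1], collapse = " ")
  cc <- nxt(); stopifnot(cc[1] == "centrosome")
  fields$centrosome <- as.numeric(cc[2:3])
  read_mat <- function(n) {
    if (i + n - 1L > length(lines)) stop("truncated snapshot file: ", path)
    block <- lines[i:(i + n - 1L)]
    i <<- i + n
    matrix(as.numeric(unlist(strsplit(block, " ", fixed = TRUE))),
           ncol = 2, byrow = TRUE)
  }
  mm <- nxt(); stopifnot(mm[1] == "membrane")
  fields$membrane <- `colnames<-`(read_mat(as.integer(mm[2])), c("x", "y"))
  nn <- nxt(); stopifnot(nn[1] == "nucleus")
  fields$nucleus <- `colnames<-`(read_mat(as.integer(nn[2])), c("x", "y"))
  nm <- nxt(); stopifnot(nm[1] == "mts")
  nmt <- as.integer(nm[2])
  fields$mts <- vector("list", nmt)
  for (k in seq_len(nmt)) {
    h <- nxt(); stopifnot(h[1] == "mt")
    fields$mts[[k]] <- list(beads = read_mat(as.integer(h[2])), state = h[3],
                            partial = as.numeric(h[4]), dir = as.numeric(h[5]),
                            dep_armed = length(h) >= 6 && h[6] == "1")
  }
  ct <- nxt(); stopifnot(ct[1] == "ctrace")
  nct <- as.integer(ct[2])
  if (nct > 0) {
    if (i + nct - 1L > length(lines)) stop("truncated snapshot file: ", path)
    fields$contract_trace <- as.numeric(lines[i:(i + nct - 1L)])
    i <- i + nct
  } else fields$contract_trace <- numeric(0)
  mo <- nxt(); stopifnot(mo[1] == "motors")
  nmo <- as.integer(mo[2])
  if (nmo > 0) {
    if (i + nmo - 1L > length(lines)) stop("truncated snapshot file: ", path)
    block <- lines[i:(i + nmo - 1L)]
    parts <- strsplit(block, " ", fixed = TRUE)
    fields$motors <- data.frame(
      loop = as.integer(vapply(parts, `[[`, "", 1)),
      bead = as.integer(vapply(parts, `[[`, "", 2)),
      bound = as.integer(vapply(parts, `[[`, "", 3)) == 1L,
      mt = ifelse(as.integer(vapply(parts, `[[`, "", 4)) < 0, NA_integer_,
                  as.integer(vapply(parts, `[[`, "", 4))),
      arc = as.numeric(vapply(parts, `[[`, "", 5)))
  } else {
    fields$motors <- data.frame(loop = integer(), bead = integer(),
                                bound = logical(), mt = integer(),
                                arc = numeric())
  }
  st <- fields[c("membrane", "nucleus", "centrosome", "mts", "motors",
                 "contract_trace", "t", "rng_mt", "rng_motor")]
  class(st) <- "cellState"
  st
}

#' Run a simulation and persist a run directory
#'
#' Thin orchestration used by the command line front end: runs
#' [simulateCell()] and writes `track.csv`, `final_state.snapshot`,
#' `config.yaml` (parameter echo), `environment.yaml` and `log.txt` into
#' `outdir`.
#'
#' @param params a `cellParams`.
#' @param env a `cellEnv`.
#' @param outdir output directory (created if needed).
#' @param ... passed to [simulateCell()].
#' @return the `cellRun`, invisibly.
#' @export
runToDirectory <- function(params, env = freeSpace(), outdir, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  run <- simulateCell(params, env, ...)
  writeTrack(run$track, file.path(outdir, "track.csv"))
  writeSnapshot(run$state, file.path(outdir, "final_state.snapshot"))
  writeParams(params, file.path(outdir, "config.yaml"))
  writeEnv(env, file.path(outdir, "environment.yaml"))
  prov <- paramProvenance(params)
  log <- c(
    sprintf("[%s] run started", format(t0)),
    sprintf("[%s] run finished: %d frames, %g simulated s",
            format(Sys.time()), nrow(run$track), max(run$track$t)),
    "parameter provenance:",
    sprintf("  %-18s = %-12g (%s)", prov$name, prov$value, prov$provenance))
  writeLines(log, file.path(outdir, "log.txt"))
  invisible(run)
}
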