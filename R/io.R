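fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read density snapshots as delimited text
#'
#' Plain-text snapshot format: `#`-prefixed header lines carrying the grid
#' metadata (mode, spacing, extents, origin, time, species count) followed
#' by one whitespace-delimited block per species with one line per grid
#' row. Values round-trip at full double precision.
#'
#' @param state A [tissue_state()].
#' @param path Output file.
#' @return `write_snapshot` returns `path` invisibly; `read_snapshot`
#'   returns the reconstructed [tissue_state()].
#' @export
write_snapshot <- function(state, path) {
  stopifnot(inherits(state, "tissue_state"))
  g <- state$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# epigrowth snapshot",
               paste("# mode:", g$mode),
               paste("# h:", fmt_num(g$h)),
               paste("# nx:", g$nx), paste("# ny:", g$ny),
               paste("# origin:", paste(fmt_num(g$origin), collapse = " ")),
               paste("# time:", fmt_num(state$time)),
               paste("# n_species:", n_species(state))), con)
  for (s in seq_len(n_species(state))) {
    writeLines(paste("# species:", s), con)
    m <- matrix(state$rho[, , s], nrow = g$nx)
    for (j in seq_len(g$ny))
      writeLines(paste(fmt_num(m[, j]), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  lines <- readLines(path)
  hdr <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), lines, value = TRUE)[1]
    trimws(sub(paste0("^# ", key, ":"), "", ln))
  }
  mode <- hdr("mode")
  h <- as.numeric(hdr("h"))
  nx <- as.integer(hdr("nx")); ny <- as.integer(hdr("ny"))
  origin <- as.numeric(strsplit(hdr("origin"), " +")[[1]])
  time <- as.numeric(hdr("time"))
  ns <- as.integer(hdr("n_species"))
  grid <- if (mode == "cartesian2d")
    fv_grid("cartesian2d", h = h, nx = nx, ny = ny, origin = origin)
  else fv_grid("radial1d", h = h, nr = nx)
  rho <- array(0, dim = c(nx, ny, ns))
  blocks <- grep("^# species:", lines)
  for (s in seq_len(ns)) {
    rows <- lines[(blocks[s] + 1):(blocks[s] + ny)]
    rho[, , s] <- t(do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), " +")[[1]]))))[, seq_len(ny) , drop = TRUE]
  }
  dim(rho) <- c(nx, ny, ns)
  tissue_state(grid, rho, time)
}

#' Write / read observation sets as delimited text
#'
#' Tab-separated columns `x`, `y`, `t`, `value` preceded by `#`-prefixed
#' metadata (voxel size, seed, generating sigma for synthetic sets, and
#' the voxel lattice geometry).
#'
#' @param obs An `observation_set`.
#' @param path Output file.
#' @return `write_observations` returns `path` invisibly;
#'   `read_observations` returns the `observation_set`.
#' @export
write_observations <- function(obs, path) {
  stopifnot(inherits(obs, "observation_set"))
  con <- file(path, "w")
  on.exit(close(con))
  lat <- obs$lattice
  writeLines(c("# epigrowth observations",
               paste("# voxel_um:", fmt_num(obs$voxel)),
               paste("# sigma_true:", fmt_num(obs$sigma)),
               paste("# seed:", obs$seed),
               paste("# lattice_corner:", paste(fmt_num(lat$corner), collapse = " ")),
               paste("# lattice_n:", lat$nvx, lat$nvy),
               "x\ty\tt\tvalue"), con)
  utils::write.table(format(obs$data, digits = 17, trim = TRUE), con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  lines <- readLines(path)
  hdr <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), lines, value = TRUE)[1]
    trimws(sub(paste0("^# ", key, ":"), "", ln))
  }
  voxel <- as.numeric(hdr("voxel_um"))
  sigma <- as.numeric(hdr("sigma_true"))
  seed <- as.integer(hdr("seed"))
  corner <- as.numeric(strsplit(hdr("lattice_corner"), " +")[[1]])
  nv <- as.integer(strsplit(hdr("lattice_n"), " +")[[1]])
  skip <- grep("^x\t", lines)[1]
  data <- utils::read.table(path, skip = skip, sep = "\t",
                            col.names = c("x", "y", "t", "value"))
  lat <- voxel_lattice(corner, nv[1] * voxel * 1e-3, nv[2] * voxel * 1e-3,
                       voxel * 1e-3)
  new_observation_set(data, voxel, sigma, seed, lat)
}

#' Write / read MCMC chains as delimited text
#'
#' Tab-separated columns `iteration`, `chain`, the four parameters,
#' `log_post`, preceded by metadata (`n_retain` convention and per-chain
#' acceptance rates).
#'
#' @param cs A [chain_set()].
#' @param path Output file.
#' @return `write_chains` returns `path` invisibly; `read_chains` returns
#'   the [chain_set()].
#' @export
write_chains <- function(cs, path) {
  stopifnot(inherits(cs, "chain_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# epigrowth chains",
               paste("# n_retain:", cs$n_retain),
               paste("# accept_rate:", paste(fmt_num(cs$accept_rate), collapse = " ")),
               paste(c("iteration", "chain", colnames(cs$chains[[1]]), "log_post"),
                     collapse = "\t")), con)
  for (c in seq_along(cs$chains)) {
    lp <- if (is.null(cs$log_post)) rep(NA_real_, cs$n_iter) else cs$log_post[, c]
    df <- data.frame(iteration = seq_len(cs$n_iter), chain = c,
                     cs$chains[[c]], log_post = lp)
    utils::write.table(format(df, digits = 17, trim = TRUE), con, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_chains
#' @export
read_chains <- function(path) {
  lines <- readLines(path, n = 20)
  n_retain <- as.integer(trimws(sub("^# n_retain:", "",
                                    grep("^# n_retain:", lines, value = TRUE)[1])))
  acc <- as.numeric(strsplit(trimws(sub("^# accept_rate:", "",
                                        grep("^# accept_rate:", lines, value = TRUE)[1])),
                             " +")[[1]])
  hdr_i <- grep("^iteration\t", lines)[1]
  tab <- utils::read.table(path, skip = hdr_i, sep = "\t")
  names(tab) <- strsplit(lines[hdr_i], "\t")[[1]]
  chains <- lapply(sort(unique(tab$chain)), function(c) {
    m <- as.matrix(tab[tab$chain == c, c("D", "r", "K", "sigma")])
    rownames(m) <- NULL
    m
  })
  lp <- do.call(cbind, lapply(sort(unique(tab$chain)),
                              function(c) tab$log_post[tab$chain == c]))
  chain_set(chains, log_post = lp, accept_rate = acc, n_retain = n_retain)
}
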