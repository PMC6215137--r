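#' Load a simulation configuration
#'
#' Reads a YAML configuration and returns validated parameter objects with
#' all unspecified keys at the reference defaults. Recognised blocks and
#' keys: `material.{Ms, a_phys, T, eta, sigma_s}`,
#' `reduced.{lambda, xi, a_red}`,
#' `geometry.{Dout, Din, dout, din, phi, n_nodes, max_particles}`,
#' `elastic.{ks, kal, kh, eps}`,
#' `integrator.{dt, mass, zeta_t, zeta_r, inertia, kT}`,
#' `protocol.{xi_values, equil_steps, measure_steps}`, and `seed`. Unknown
#' keys are rejected. If both `material` and `reduced` are given, the
#' reduced values win and a consistency warning is raised.
#'
#' @param path YAML file path.
#' @return List with `spec` ([system_spec()]), `forcefield`
#'   ([forcefield_params()]), `integrator` ([integrator_config()]),
#'   `protocol` ([field_protocol()]), `reduced` ([reduced_params()]), and
#'   `seed`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  schema <- list(
    material = c("Ms", "a_phys", "T", "eta", "sigma_s"),
    reduced = c("lambda", "xi", "a_red"),
    geometry = c("Dout", "Din", "dout", "din", "phi", "n_nodes",
                 "max_particles"),
    elastic = c("ks", "kal", "kh", "eps"),
    integrator = c("dt", "mass", "zeta_t", "zeta_r", "inertia", "kT"),
    protocol = c("xi_values", "equil_steps", "measure_steps"),
    seed = NULL)
  bad_blocks <- setdiff(names(raw), names(schema))
  if (length(bad_blocks))
    stop("unknown configuration keys: ", paste(bad_blocks, collapse = ", "))
  for (blk in intersect(names(raw), names(schema))) {
    if (is.null(schema[[blk]])) next
    bad <- setdiff(names(raw[[blk]]), schema[[blk]])
    if (length(bad))
      stop(sprintf("unknown keys in '%s': %s", blk, paste(bad, collapse = ", ")))
  }

  red <- NULL
  if (!is.null(raw$material)) {
    mat <- do.call(material_params, raw$material)
    red <- reduced_from_material(mat,
                                 a_red = raw$reduced$a_red %||% 1.2)
  }
  if (!is.null(raw$reduced)) {
    if (!is.null(red))
      warning("both material and reduced blocks given; reduced values win")
    rr <- raw$reduced
    red <- reduced_params(lambda = rr$lambda %||% (red$lambda %||% 1),
                          xi = rr$xi %||% 0,
                          a_red = rr$a_red %||% 1.2,
                          length_unit = red$length_unit %||% (1e-8 / 1.2))
  }
  if (is.null(red)) red <- reduced_params(lambda = 1, xi = 0)
  if (red$lambda < 0) stop("negative lambda is not valid")

  g <- raw$geometry %||% list()
  spec <- system_spec(Dout = g$Dout %||% 24, Din = g$Din %||% 16,
                      dout = g$dout %||% 3.1, din = g$din %||% 2,
                      a_red = red$a_red, phi = g$phi %||% 0.055,
                      n_nodes = g$n_nodes %||% 393,
                      max_particles = g$max_particles %||% 393)
  el <- raw$elastic %||% list()
  ff <- forcefield_params(ks = el$ks %||% 1, kal = el$kal %||% 1,
                          kh = el$kh %||% 1, eps = el$eps %||% 1,
                          lambda = red$lambda, xi = red$xi)
  it <- raw$integrator %||% list()
  cfg <- integrator_config(dt = it$dt %||% 0.005, mass = it$mass %||% 1,
                           zeta_t = it$zeta_t %||% 1,
                           zeta_r = it$zeta_r,
                           inertia = it$inertia %||% 1, kT = it$kT %||% 1)
  pr <- raw$protocol %||% list()
  protocol <- field_protocol(
    xi_values = unlist(pr$xi_values) %||% c(0, 0.5, 1, 2, 3, 5, 7, 10),
    equil_steps = pr$equil_steps %||% 10000,
    measure_steps = pr$measure_steps %||% 10000)
  list(spec = spec, forcefield = ff, integrator = cfg, protocol = protocol,
       reduced = red, seed = raw$seed %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a configuration back to YAML
#'
#' Writes the blocks accepted by [load_config()]; `load_config()` of the
#' written file reproduces the same parameter objects.
#'
#' @param config list as returned by [load_config()].
#' @param path output path.
#' @export
save_config <- function(config, path) {
  out <- list(
    reduced = list(lambda = config$reduced$lambda, xi = config$reduced$xi,
                   a_red = config$reduced$a_red),
    geometry = list(Dout = config$spec$Dout, Din = config$spec$Din,
                    dout = config$spec$dout, din = config$spec$din,
                    phi = config$spec$phi, n_nodes = config$spec$n_nodes,
                    max_particles = config$spec$max_particles),
    elastic = list(ks = config$forcefield$ks, kal = config$forcefield$kal,
                   kh = config$forcefield$kh, eps = config$forcefield$eps),
    integrator = list(dt = config$integrator$dt, mass = config$integrator$mass,
                      zeta_t = config$integrator$zeta_t,
                      inertia = config$integrator$inertia,
                      kT = config$integrator$kT),
    protocol = list(xi_values = config$protocol$xi_values,
                    equil_steps = config$protocol$equil_steps,
                    measure_steps = config$protocol$measure_steps))
  if (!is.null(config$integrator$zeta_r))
    out$integrator$zeta_r <- config$integrator$zeta_r
  if (!is.null(config$seed)) out$seed <- config$seed
  yaml::write_yaml(out, path)
  invisible(path)
}

# stable content hash (Adler-32 over the serialised object)
.config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  a <- 1; b <- 0
  for (v in bytes) {
    a <- (a + v) %% 65521
    b <- (b + a) %% 65521
  }
  sprintf("%04x%04x", b, a)
}

#' Write a trajectory as extended XYZ
#'
#' One block per frame: element count, a comment line with
#' `Properties=species:S:1:pos:R:3:orient:R:3` and the frame time, then one
#' line per element (`B` for blobs with zero orientation, `M` for
#' nanoparticles with their dipole orientation). Plain text, readable by
#' standard viewers.
#'
#' @param frames list of [mps_state()] objects (or a single state).
#' @param path output path.
#' @export
write_trajectory <- function(frames, path) {
  if (inherits(frames, "mps_state")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (st in frames) {
    n <- .state_counts(st)
    pos <- .state_positions(st)
    N <- nrow(pos)
    writeLines(as.character(N), con)
    writeLines(sprintf(
      "Properties=species:S:1:pos:R:3:orient:R:3 Time=%.10g", st$time), con)
    species <- c(rep("B", n$n_out + n$n_in), rep("M", n$n_mnp))
    orient <- rbind(matrix(0, n$n_out + n$n_in, 3), st$particles$orient)
    writeLines(sprintf("%s %.10g %.10g %.10g %.10g %.10g %.10g",
                       species, pos[, 1], pos[, 2], pos[, 3],
                       orient[, 1], orient[, 2], orient[, 3]), con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' Inverse of [write_trajectory()]; returns the raw frame contents (element
#' species, positions, orientations, time), not full states.
#'
#' @param path file path.
#' @return List of frames, each with `species`, `pos`, `orient`, `time`.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    N <- as.integer(lines[i])
    tm <- as.numeric(sub(".*Time=([-0-9.eE+]+).*", "\\1", lines[i + 1]))
    rows <- strsplit(lines[i + 1 + seq_len(N)], " +")
    species <- vapply(rows, `[[`, "", 1)
    num <- t(vapply(rows, function(r) as.numeric(r[2:7]), numeric(6)))
    frames[[length(frames) + 1]] <-
      list(species = species, pos = num[, 1:3, drop = FALSE],
           orient = num[, 4:6, drop = FALSE], time = tm)
    i <- i + 2 + N
  }
  frames
}

#' Checkpoint and restore a simulation
#'
#' `checkpoint_state()` stores the full state, the RNG state, a manifest
#' (stage tag, seeds, package version) and a hash of the configuration;
#' `restore_state()` reloads it, restores the RNG stream and verifies the
#' configuration hash, so a restored run continues bitwise-identically.
#'
#' @param state an [mps_state()].
#' @param path checkpoint file path.
#' @param config configuration list (hashed into the checkpoint).
#' @param stage protocol stage tag (`"pre"`, `"ground"`, `"ramp"`, ...).
#' @param manifest optional extra manifest entries.
#' @export
checkpoint_state <- function(state, path, config = NULL, stage = "pre",
                             manifest = list()) {
  rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  obj <- list(state = state, rng = rng,
              config_hash = .config_hash(config),
              manifest = c(list(stage = stage,
                                package_version =
                                  as.character(utils::packageVersion("mpsdyn")),
                                time = state$time),
                           manifest))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname checkpoint_state
#' @param override skip the configuration-hash check.
#' @export
restore_state <- function(path, config = NULL, override = FALSE) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupted checkpoint: ",
                                           conditionMessage(e)))
  if (!is.list(obj) || is.null(obj$state) || !inherits(obj$state, "mps_state"))
    stop("corrupted checkpoint: missing state")
  if (!override && !identical(obj$config_hash, .config_hash(config)))
    stop("checkpoint/config hash mismatch; pass override = TRUE to force")
  if (!is.null(obj$rng))
    assign(".Random.seed", obj$rng, envir = globalenv())
  obj
}
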