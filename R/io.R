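# Plain-text serialization: DCF key-value configs, CSV artifacts written
# at full double precision (%.17g) so write/read round-trips are lossless.

config_keys <- list(
  bath = c("density", "box_length", "n_particles", "speed",
           "rot_diffusivity", "circ_frequency", "dt"),
  train = c("learning_rate", "discount", "reward_magnitude",
            "episodes_per_cycle", "n_cycles", "t_max", "perception_time",
            "scan_radius"),
  potential = c("r_min", "friction", "amplitude")
)

#' Load a run configuration file
#'
#' Configs are DCF text files (`key: value` lines) whose keys mirror the
#' parameter object fields; any key may be omitted, in which case the
#' reference defaults apply (density 0.6, box 25, speed 1.5, dt 1/6,
#' learning rate 0.01, discount 0.9, ...). Unknown keys and unparsable
#' values are rejected by name.
#'
#' @param path path to the config file; `NULL` gives the full defaults.
#' @return A list with elements `bath` ([bath_params()]), `train`
#'   ([train_config()]), `potential` (list of potential-model scalars) and
#'   `theory` (list of scalars consumed by the theory functions).
#' @export
load_config <- function(path = NULL) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- tryCatch(read.dcf(path), error = function(e) {
      stop("cannot parse config file ", path, ": ", conditionMessage(e))
    })
    if (nrow(raw) > 0) {
      vals <- as.list(raw[1, ])
      known <- unlist(config_keys, use.names = FALSE)
      unknown <- setdiff(names(vals), known)
      if (length(unknown) > 0) {
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
      }
      vals <- lapply(vals, function(v) {
        num <- suppressWarnings(as.numeric(v))
        num
      })
      bad <- names(vals)[vapply(vals, is.na, logical(1))]
      if (length(bad) > 0) {
        stop("non-numeric value for config key(s): ",
             paste(bad, collapse = ", "))
      }
    }
  }
  take <- function(keys) vals[intersect(keys, names(vals))]
  bath <- do.call(bath_params, take(config_keys$bath))
  train <- do.call(train_config, take(config_keys$train))
  check_timestep(train, bath)
  pot_defaults <- list(r_min = train$scan_radius / 20, friction = 1,
                       amplitude = 5)
  pot <- utils::modifyList(pot_defaults, take(config_keys$potential))
  if (pot$r_min <= 0 || pot$r_min >= train$scan_radius) {
    stop("invalid config key r_min: need 0 < r_min < scan_radius")
  }
  theory <- list(density = bath$density, box_length = bath$box_length,
                 scan_radius = train$scan_radius,
                 perception_time = train$perception_time,
                 speed = bath$speed,
                 rot_diffusivity = bath$rot_diffusivity)
  list(bath = bath, train = train, potential = pot, theory = theory)
}

#' Write a configuration file
#'
#' @param bath a [bath_params()] object.
#' @param train a [train_config()] object.
#' @param potential optional list with `r_min`, `friction`, `amplitude`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(bath, train, path, potential = NULL) {
  stopifnot(inherits(bath, "bath_params"), inherits(train, "train_config"))
  fields <- c(
    bath[setdiff(config_keys$bath, "n_particles")],
    train[config_keys$train],
    potential[intersect(names(potential), config_keys$potential)]
  )
  lines <- sprintf("%s: %.17g", names(fields), as.numeric(unlist(fields)))
  writeLines(lines, path)
  invisible(path)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Read and write Q matrices as CSV
#'
#' Two columns (`no_go`, `go`), one row per orientation state, full
#' double precision.
#'
#' @param q a 360 x 2 Q matrix.
#' @param path file path.
#' @return `read_qmatrix` returns the matrix; `write_qmatrix` returns
#'   `path` invisibly.
#' @export
write_qmatrix <- function(q, path) {
  stopifnot(is.matrix(q), ncol(q) == 2)
  writeLines(c("no_go,go",
               paste(fmt_num(q[, 1]), fmt_num(q[, 2]), sep = ",")), path)
  invisible(path)
}

#' @rdname write_qmatrix
#' @export
read_qmatrix <- function(path) {
  df <- read.csv(path)
  stopifnot(identical(names(df), c("no_go", "go")))
  as.matrix(df)
}

#' Read and write decision diagrams
#'
#' The CSV holds one row per orientation bin (`bin`, `h_go`, `go_mask`);
#' the optional JSON summary stores the arc descriptors and cycle count.
#'
#' @param diagram a [decision_diagram()].
#' @param path CSV path.
#' @param json_path optional path for the JSON summary.
#' @return `read_diagram` returns the reconstructed diagram;
#'   the writer returns `path` invisibly.
#' @export
write_diagram <- function(diagram, path, json_path = NULL) {
  stopifnot(inherits(diagram, "decision_diagram"))
  writeLines(c("bin,h_go,go_mask",
               paste(seq_len(360), fmt_num(diagram$h_go),
                     as.integer(diagram$go_mask), sep = ",")), path)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(phi0 = diagram$phi0, dphi = diagram$dphi,
           n_cycles = diagram$n_cycles),
      json_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' @rdname write_diagram
#' @export
read_diagram <- function(path) {
  df <- read.csv(path)
  stopifnot(identical(names(df), c("bin", "h_go", "go_mask")))
  d <- decision_diagram(df$h_go[order(df$bin)])
  if (!all(d$go_mask == as.logical(df$go_mask[order(df$bin)]))) {
    stop("inconsistent diagram file: stored mask disagrees with h_go")
  }
  d
}

#' Read and write trajectories as CSV
#'
#' Columns `time`, `x`, `y` and (if present) `partner`.
#'
#' @param traj an `ihp_trajectory`.
#' @param path file path.
#' @return `read_trajectory` returns the trajectory; the writer returns
#'   `path` invisibly.
#' @export
write_trajectory <- function(traj, path) {
  has_partner <- "partner" %in% names(traj)
  if (has_partner) {
    writeLines(c("time,x,y,partner",
                 paste(fmt_num(traj$time), fmt_num(traj$x), fmt_num(traj$y),
                       ifelse(is.na(traj$partner), "", traj$partner),
                       sep = ",")), path)
  } else {
    writeLines(c("time,x,y",
                 paste(fmt_num(traj$time), fmt_num(traj$x), fmt_num(traj$y),
                       sep = ",")), path)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("time", "x", "y") %in% names(df)))
  if ("partner" %in% names(df)) df$partner <- as.integer(df$partner)
  new_ihp_trajectory(df)
}

#' Reproducibility manifest for a run
#'
#' Collects every parameter and derived seed of a run into one list;
#' written as JSON it suffices to reproduce the run bitwise with the same
#' build.
#'
#' @param bath a [bath_params()] object.
#' @param config a [train_config()] object.
#' @param seed base seed.
#' @param cycle_seeds derived per-cycle seeds.
#' @param extra optional named list of additional entries.
#' @param path if non-`NULL`, also write the manifest there as JSON.
#' @return The manifest list, invisibly if written.
#' @export
run_manifest <- function(bath, config, seed, cycle_seeds = NULL,
                         extra = NULL, path = NULL) {
  m <- list(
    package_version = as.character(utils::packageVersion("ihp")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    bath = unclass(bath),
    train = unclass(config),
    seed = seed,
    cycle_seeds = cycle_seeds
  )
  if (!is.null(extra)) m <- c(m, extra)
  if (!is.null(path)) {
    jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(m))
  }
  m
}

#' Deterministic scripted fixtures
#'
#' Named, fully deterministic configurations used as test oracles:
#' \describe{
#'   \item{`"empty"`}{a bath with zero particles.}
#'   \item{`"single-upward-abp"`}{one noiseless particle at `(0, 0.5)`
#'     moving straight up (`phi = pi/2`).}
#'   \item{`"single-downward-abp"`}{one noiseless particle at `(0, 0.5)`
#'     moving straight down.}
#'   \item{`"circling-abp"`}{one noiseless chiral particle
#'     (`omega = 2 pi / 10`) tracing a circle of radius `v0 / omega` that
#'     closes after one period `2 pi / omega`.}
#'   \item{`"toy-mdp"`}{a deterministic two-state decision process with
#'     terminal rewards of 100, for checking the tabular learner against
#'     value iteration.}
#' }
#'
#' @param name fixture name.
#' @return For bath fixtures, a list (class `scripted_bath`) with
#'   `params` ([bath_params()], noiseless) and `state` (`bath_state`);
#'   for `"toy-mdp"`, a `toy_mdp` list.
#' @export
make_fixture <- function(name) {
  switch(name,
    "empty" = {
      p <- bath_params(density = 0, rot_diffusivity = 0)
      structure(list(name = name, params = p,
                     state = new_bath_state(
                       matrix(numeric(0), ncol = 2,
                              dimnames = list(NULL, c("x", "y"))),
                       numeric(0), 0, p$box_length)),
                class = "scripted_bath")
    },
    "single-upward-abp" = scripted_single(name, c(0, 0.5), pi / 2),
    "single-downward-abp" = scripted_single(name, c(0, 0.5), 3 * pi / 2),
    "circling-abp" = scripted_single(name, c(5, 5), 0,
                                     circ_frequency = 2 * pi / 10),
    "toy-mdp" = {
      # state 1, GO -> state 2; state 2, GO -> goal (+100);
      # state 1, NO GO -> bottom (-100); state 2, NO GO -> state 1.
      structure(list(
        n_states = 2L,
        next_state = matrix(c(0L, 1L, 2L, 0L), nrow = 2,
                            dimnames = list(NULL, c("no_go", "go"))),
        reward = matrix(c(-100, 0, 0, 100), nrow = 2,
                        dimnames = list(NULL, c("no_go", "go"))),
        start = 1L
      ), class = "toy_mdp")
    },
    stop("unknown fixture: ", name)
  )
}

scripted_single <- function(name, pos, phi, circ_frequency = 0) {
  p <- bath_params(n_particles = 1, rot_diffusivity = 0,
                   circ_frequency = circ_frequency)
  structure(
    list(name = name, params = p,
         state = new_bath_state(
           matrix(pos, ncol = 2, dimnames = list(NULL, c("x", "y"))),
           phi %% (2 * pi), 0, p$box_length)),
    class = "scripted_bath"
  )
}
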