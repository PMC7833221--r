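# Game of Life particle collider: B3/S23 simulator (toroidal boundary, so
# drifting spaceships persist and the state space stays exactly {0,1}^(H*W)),
# a particle template library built by direct evolution, translation /
# rotation / reflection / phase-invariant particle detection, and the
# two-particle collider ensemble.

#' Create an empty Game of Life board
#'
#' @param h,w board dimensions (default 15 x 15).
#' @return an integer 0/1 matrix.
#' @export
gol_board <- function(h = 15, w = 15) matrix(0L, h, w)

#' Advance a Game of Life board
#'
#' Applies the Conway B3/S23 rule synchronously with wrap-around
#' (toroidal) boundary conditions.
#'
#' @param board 0/1 integer matrix.
#' @param steps number of generations (default 1).
#' @return the evolved board.
#' @export
gol_step <- function(board, steps = 1) {
  stopifnot(is.matrix(board), all(board %in% c(0L, 1L)))
  gol_evolve_cpp(matrix(as.integer(board), nrow(board), ncol(board)), steps)
}

# ---- pattern plumbing ----------------------------------------------------

# parse a .cells-style block ('.' dead, 'O' alive) into an offset matrix
parse_cells <- function(text) {
  rows <- strsplit(text, "\n")[[1]]
  rows <- rows[nzchar(rows)]
  cells <- do.call(rbind, lapply(seq_along(rows), function(i) {
    ch <- strsplit(rows[i], "")[[1]]
    j <- which(ch == "O")
    if (length(j)) cbind(r = i - 1L, c = j - 1L)
  }))
  canon_offsets(cells)
}

canon_offsets <- function(cells) {
  cells[, 1] <- cells[, 1] - min(cells[, 1])
  cells[, 2] <- cells[, 2] - min(cells[, 2])
  cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
}

offsets_key <- function(cells) paste(cells[, 1], cells[, 2], sep = ",", collapse = ";")

place_offsets <- function(board, cells, r0, c0) {
  board[cbind(cells[, 1] + r0 + 1L, cells[, 2] + c0 + 1L)] <- 1L
  board
}

board_offsets <- function(board) {
  idx <- which(board == 1L, arr.ind = TRUE)
  cbind(r = idx[, 1] - 1L, c = idx[, 2] - 1L)
}

# the dihedral group of the square as 2x2 integer matrices acting on (r, c)
square_symmetries <- function() {
  rot <- matrix(c(0L, 1L, -1L, 0L), 2)     # (r,c) -> (-c, r)
  flip <- matrix(c(1L, 0L, 0L, -1L), 2)    # (r,c) -> (r, -c)
  out <- list(); m <- diag(2L)
  for (i in 1:4) { out[[length(out) + 1]] <- m; out[[length(out) + 1]] <- flip %*% m; m <- rot %*% m }
  out
}

apply_symmetry <- function(cells, M) canon_offsets(t(M %*% t(cells)))

# built-in pattern set: the two canonical small spaceships plus the small
# oscillator/still-life "debris" vocabulary
builtin_patterns <- function() {
  list(
    glider  = ".O.\n..O\nOOO",
    lwss    = ".O..O\nO....\nO...O\nOOOO.",
    blinker = "OOO",
    block   = "OO\nOO",
    beehive = ".OO.\nO..O\n.OO.",
    loaf    = ".OO.\nO..O\n.O.O\n..O.",
    boat    = "OO.\nO.O\n.O.",
    tub     = ".O.\nO.O\n.O.",
    ship    = "OO.\nO.O\n.OO"
  )
}

# evolve a pattern on a large empty board to recover its phase cycle and
# per-period velocity; errors if the pattern is not periodic within
# `max_period` steps (the library's load-time self-test)
pattern_phases <- function(cells, max_period = 8, size = 32) {
  b <- place_offsets(gol_board(size, size), cells, 12L, 12L)
  phases <- list(canon_offsets(board_offsets(b)))
  key0 <- offsets_key(phases[[1]])
  pos0 <- c(min(board_offsets(b)[, 1]), min(board_offsets(b)[, 2]))
  for (s in seq_len(max_period)) {
    b <- gol_step(b)
    off <- board_offsets(b)
    if (nrow(off) == 0) stop("pattern died: not a particle")
    can <- canon_offsets(off)
    if (offsets_key(can) == key0) {
      vel <- c(min(off[, 1]), min(off[, 2])) - pos0
      return(list(phases = phases, period = s, velocity = vel))
    }
    phases[[length(phases) + 1]] <- can
  }
  stop("pattern did not return to its initial phase within max_period steps")
}

#' Particle template library
#'
#' Builds (and caches) the particle library: for every pattern, all phases
#' of its oscillation recovered by direct evolution, expanded over the 8
#' symmetries of the square, with per-variant velocities.  Library
#' validity is self-tested at build time: every phase must advance to the
#' next under one evolution step.
#'
#' @param patterns named character vector/list of .cells-style blocks
#'   ('.' = dead, 'O' = alive, one row per line); default: glider, LWSS,
#'   blinker, block, beehive, loaf, boat, tub, ship.
#' @param initial_types names of the types used to seed collider trials
#'   (default: glider, lwss, blinker, block); the remaining types extend
#'   the detection vocabulary for post-collision debris.
#' @return an object of class `gol_library`.
#' @export
gol_library <- function(patterns = builtin_patterns(),
                        initial_types = c("glider", "lwss", "blinker", "block")) {
  stopifnot(all(initial_types %in% names(patterns)))
  syms <- square_symmetries()
  types <- names(patterns)
  key_map <- new.env(hash = TRUE, parent = emptyenv())
  variants <- list()
  for (ty in types) {
    ph <- pattern_phases(parse_cells(patterns[[ty]]))
    vs <- list()
    for (M in syms) for (i in seq_along(ph$phases)) {
      cells <- apply_symmetry(ph$phases[[i]], M)
      key <- offsets_key(cells)
      if (is.null(key_map[[key]])) key_map[[key]] <- ty
      vs[[length(vs) + 1]] <- list(cells = cells,
                                   velocity = as.vector(M %*% ph$velocity),
                                   period = ph$period, phase = i)
    }
    # drop duplicate variants (symmetric patterns repeat under the group)
    keys <- vapply(vs, function(v) offsets_key(v$cells), character(1))
    variants[[ty]] <- vs[!duplicated(keys)]
  }
  structure(list(types = types, initial_types = initial_types,
                 variants = variants, key_map = key_map),
            class = "gol_library")
}

#' @export
print.gol_library <- function(x, ...) {
  cat("<gol_library> types:", paste(x$types, collapse = ", "), "\n")
  invisible(x)
}

#' Read a particle pattern library from a plain-text file
#'
#' The file holds one .cells-style block per pattern: a header line
#' `! name` followed by rows of `.` (dead) and `O` (alive); blocks are
#' separated by the next `!` header.  Lines starting with `#` are
#' comments.  See `system.file("extdata", "particles.cells", package =
#' "emergence")` for the built-in set in this format.
#'
#' @param path file path.
#' @param initial_types passed to [gol_library()]; defaults to every
#'   pattern in the file.
#' @return a [gol_library].
#' @export
read_pattern_library <- function(path, initial_types = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  pats <- list()
  cur <- NULL
  for (ln in lines) {
    if (grepl("^!", ln)) {
      cur <- trimws(sub("^!", "", ln))
      pats[[cur]] <- character()
    } else if (nzchar(trimws(ln))) {
      if (is.null(cur)) stop("pattern rows before the first '! name' header")
      if (grepl("[^.O]", ln)) stop(sprintf("invalid pattern row: '%s'", ln))
      pats[[cur]] <- c(pats[[cur]], ln)
    }
  }
  if (!length(pats)) stop("no patterns found in ", path)
  pats <- lapply(pats, paste, collapse = "\n")
  gol_library(pats, initial_types = initial_types %||% names(pats))
}

the_library <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- gol_library()
    cache
  }
})

# ---- detection -----------------------------------------------------------

# toroidal shift of a matrix by (dr, dc)
shift_torus <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  m[(seq_len(H) - 1 - dr) %% H + 1, (seq_len(W) - 1 - dc) %% W + 1, drop = FALSE]
}

# one morphological dilation step (toroidal, 8-neighbourhood)
dilate_board <- function(board) {
  nb <- board
  for (dr in -1:1) for (dc in -1:1)
    if (dr || dc) nb <- nb + shift_torus(board, dr, dc)
  (nb > 0) + 0L
}

# Group live cells into particles: connected components of the dilated
# board, so that cells within Chebyshev distance 2 belong to one particle.
# (Some spaceship phases -- the LWSS among them -- are not 8-connected, while
# genuinely separate particles keep a 2-cell dead moat.)
particle_groups <- function(board) {
  comps <- board_components(dilate_board(board))
  out <- list()
  for (cells in comps) {
    live <- cells[board[cells] == 1L, , drop = FALSE]
    if (nrow(live)) out[[length(out) + 1]] <- live
  }
  out
}

# connected components of live cells (8-connectivity, toroidal)
board_components <- function(board) {
  H <- nrow(board); W <- ncol(board)
  lab <- matrix(0L, H, W)
  comp <- list()
  live <- which(board == 1L, arr.ind = TRUE)
  for (s in seq_len(nrow(live))) {
    i0 <- live[s, 1]; j0 <- live[s, 2]
    if (lab[i0, j0]) next
    id <- length(comp) + 1L
    stack <- list(c(i0, j0)); lab[i0, j0] <- id
    cells <- matrix(0L, 0, 2)
    while (length(stack)) {
      ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      cells <- rbind(cells, ij)
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ni <- (ij[1] - 1 + di) %% H + 1; nj <- (ij[2] - 1 + dj) %% W + 1
        if (board[ni, nj] == 1L && !lab[ni, nj]) {
          lab[ni, nj] <- id
          stack[[length(stack) + 1]] <- c(ni, nj)
        }
      }
    }
    comp[[id]] <- cells
  }
  comp
}

# canonicalise a component's cells (1-based board coords) on the torus:
# rotate rows/cols so the component is contiguous, then translate to origin
canon_component <- function(cells, H, W) {
  r <- cells[, 1] - 1L; c <- cells[, 2] - 1L
  shift_axis <- function(v, n) {
    occ <- sort(unique(v))
    if (length(occ) == n) return(NULL)      # spans the whole torus
    gap <- setdiff(0:(n - 1), occ)[1]
    (v - gap - 1L) %% n
  }
  r2 <- shift_axis(r, H); c2 <- shift_axis(c, W)
  if (is.null(r2) || is.null(c2)) return(NULL)
  canon_offsets(cbind(r = r2, c = c2))
}

#' Detect particle types on a board
#'
#' Matches every connected group of live cells against the library,
#' invariantly to translation, rotation, reflection and oscillation phase.
#'
#' @param board 0/1 matrix.
#' @param library a [gol_library] (default: the built-in library).
#' @return named 0/1 integer vector, one entry per library type
#'   (`V[j] = 1` iff a particle of type j is present anywhere on the
#'   board).  Attribute `unrecognised_mass` counts live cells belonging to
#'   unmatched components.
#' @export
detect_types <- function(board, library = the_library()) {
  v <- stats::setNames(integer(length(library$types)), library$types)
  unrec <- 0L
  for (cells in particle_groups(board)) {
    can <- canon_component(cells, nrow(board), ncol(board))
    ty <- if (is.null(can)) NULL else library$key_map[[offsets_key(can)]]
    if (is.null(ty)) unrec <- unrec + nrow(cells) else v[ty] <- 1L
  }
  attr(v, "unrecognised_mass") <- unrec
  v
}

# ---- collider ensemble ---------------------------------------------------

#' Initialise a two-particle collider board
#'
#' Places two particles of randomly chosen type (from the library's
#' `initial_types`), randomised position, phase and vertical displacement,
#' on opposite halves of the board.  Moving particles are oriented to face
#' each other (horizontal velocity pointing at the opposing particle);
#' stationary types take a random orientation.  The placement is validated
#' by [detect_types()] and re-drawn if the particles touch.
#'
#' @param seed integer seed (required; the board is a deterministic
#'   function of it).
#' @param library a [gol_library].
#' @param h,w board dimensions.
#' @return a board matrix with attributes `types` (the two chosen type
#'   names) and `v` (the initial type vector).
#' @export
init_collider <- function(seed, library = the_library(), h = 15, w = 15) {
  if (missing(seed)) stop("`seed` is required")
  withr_seed(seed, init_collider_impl(library, h, w))
}

init_collider_impl <- function(library, h, w) {
  pick_variant <- function(ty, want_vx) {
    vs <- library$variants[[ty]]
    vx <- vapply(vs, function(v) v$velocity[2], numeric(1))
    moving <- any(vx != 0)
    ok <- if (moving) which(sign(vx) == want_vx) else seq_along(vs)
    vs[[ok[sample.int(length(ok), 1)]]]
  }
  half <- floor(w / 2)
  tys <- sample(library$initial_types, 2, replace = TRUE)
  for (try in 1:100) {
    va <- pick_variant(tys[1], +1)          # left particle, heading right
    vb <- pick_variant(tys[2], -1)          # right particle, heading left
    dims <- function(v) c(max(v$cells[, 1]) + 1L, max(v$cells[, 2]) + 1L)
    da <- dims(va); db <- dims(vb)
    if (half - 1 - da[2] < 0 || w - db[2] - (half + 1) < 0) next
    ra <- sample.int(h - da[1], 1) - 1L
    ca <- sample.int(half - 1 - da[2] + 1, 1) - 1L
    rb <- sample.int(h - db[1], 1) - 1L
    cb <- half + 1L + sample.int(w - db[2] - half, 1) - 1L
    b <- place_offsets(place_offsets(gol_board(h, w), va$cells, ra, ca),
                       vb$cells, rb, cb)
    v <- detect_types(b, library)
    if (attr(v, "unrecognised_mass") == 0L &&
        setequal(names(v)[v == 1L], tys) && sum(b) == nrow(va$cells) + nrow(vb$cells)) {
      attr(b, "types") <- tys
      attr(b, "v") <- v
      return(b)
    }
  }
  stop("could not place two non-interacting particles after 100 attempts")
}

#' Run the particle-collider ensemble
#'
#' Generates `trials` independent collider boards, evolves each for
#' `steps` generations, and records the board and the particle-type vector
#' at both ends.  The resulting ensemble feeds [emergence()]; use the
#' jackknife estimator there, since the analysis sums 225 cell-wise MI
#' terms whose plug-in small-sample bias would otherwise swamp the signal.
#'
#' @param trials number of independent trials (default 2000).
#' @param steps generations between t and t' (default 1000; long enough
#'   for the collision products to settle).
#' @param seed integer seed; trial b uses sub-seed derived
#'   deterministically from it.
#' @param library a [gol_library].
#' @param h,w board dimensions.
#' @return an object of class `gol_experiment`: list with binary matrices
#'   `v_t`, `v_tp` (trials x types) and `x_t`, `x_tp` (trials x cells).
#' @export
run_collider_experiment <- function(trials = 2000, steps = 1000, seed,
                                    library = the_library(), h = 15, w = 15) {
  if (missing(seed)) stop("`seed` is required")
  L <- length(library$types)
  v_t <- matrix(0L, trials, L, dimnames = list(NULL, library$types))
  v_tp <- v_t
  x_t <- matrix(0L, trials, h * w)
  x_tp <- x_t
  sub_seeds <- withr_seed(seed, sample.int(.Machine$integer.max - 1, trials))
  for (b in seq_len(trials)) {
    board <- init_collider(sub_seeds[b], library, h, w)
    v_t[b, ] <- as.integer(attr(board, "v"))
    x_t[b, ] <- as.integer(board)
    final <- if (steps > 0) gol_step(board, steps) else board
    v_tp[b, ] <- as.integer(detect_types(final, library))
    x_tp[b, ] <- as.integer(final)
  }
  structure(list(v_t = v_t, v_tp = v_tp, x_t = x_t, x_tp = x_tp,
                 trials = trials, steps = steps, seed = seed,
                 types = library$types, h = h, w = w),
            class = "gol_experiment")
}

#' @export
print.gol_experiment <- function(x, ...) {
  cat(sprintf("<gol_experiment> %d trials, %d steps, %dx%d board\n",
              x$trials, x$steps, x$h, x$w))
  invisible(x)
}

#' Convert a collider experiment to criteria inputs
#'
#' @param x a `gol_experiment`.
#' @return list with `system` and `feature` [sample_matrix] objects
#'   (trials x 2 timepoints x variables) ready for [emergence()] at
#'   `tau = 1`.
#' @export
collider_samples <- function(x) {
  stopifnot(inherits(x, "gol_experiment"))
  n <- x$trials
  sys <- array(0L, c(n, 2, ncol(x$x_t)))
  sys[, 1, ] <- x$x_t; sys[, 2, ] <- x$x_tp
  feat <- array(0L, c(n, 2, ncol(x$v_t)))
  feat[, 1, ] <- x$v_t; feat[, 2, ] <- x$v_tp
  list(system = sample_matrix(sys, "discrete", card = 2L,
                              vars = paste0("c", seq_len(ncol(x$x_t)))),
       feature = sample_matrix(feat, "discrete", card = 2L, vars = x$types))
}
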