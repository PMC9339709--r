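# Electrode geometry for the 22-channel 10/20 montage and spherical-spline
# channel interpolation (Perrin-style surface splines on the unit sphere).

# Idealized 10/20 angles: theta = polar angle from the vertex (Cz), phi =
# azimuth from the anterior midline, positive towards the right ear.
.montage_1020 <- local({
  tab <- rbind(
    c("Fp1", 72, -18), c("Fp2", 72, 18),
    c("AFz", 54, 0),
    c("F3", 48, -41), c("Fz", 36, 0), c("F4", 48, 41),
    c("T7", 72, -90), c("C3", 36, -90), c("Cz", 0, 0), c("C4", 36, 90),
    c("T8", 72, 90),
    c("CPz", 18, 180),
    c("P7", 72, -126), c("P3", 48, -139), c("Pz", 36, 180),
    c("P4", 48, 139), c("P8", 72, 126),
    c("POz", 54, 180),
    c("O1", 72, -162), c("O2", 72, 162),
    c("M1", 108, -103), c("M2", 108, 103)
  )
  data.frame(label = tab[, 1],
             theta = as.numeric(tab[, 2]),
             phi = as.numeric(tab[, 3]),
             stringsAsFactors = FALSE)
})

#' Standard 10/20 montage positions
#'
#' Unit-sphere positions (x = right, y = anterior, z = superior) for the
#' 22-channel wireless montage used throughout the package
#' (Fp1...M2, vertex at Cz).
#'
#' @param labels channel labels; defaults to the full 22-channel set.
#' @return data.frame with columns `label`, `x`, `y`, `z`.
#' @export
standard_montage <- function(labels = .montage_1020$label) {
  idx <- match(labels, .montage_1020$label)
  if (anyNA(idx)) {
    stop_input("unknown channel label(s): %s",
               paste(labels[is.na(idx)], collapse = ", "))
  }
  m <- .montage_1020[idx, ]
  th <- deg2rad(m$theta)
  ph <- deg2rad(m$phi)
  data.frame(label = m$label,
             x = sin(th) * sin(ph),
             y = sin(th) * cos(ph),
             z = cos(th),
             stringsAsFactors = FALSE)
}

#' Default 22-channel label set
#' @export
default_channels <- function() .montage_1020$label

# Legendre-series Green's function for spherical splines (stiffness m = 4).
.spline_g <- function(cosang, m = 4, n_terms = 50) {
  p_nm1 <- rep(1, length(cosang))  # P_0
  p_n <- cosang                    # P_1
  g <- (2 * 1 + 1) / (1^m * 2^m) * p_n
  for (n in 2:n_terms) {
    p_np1 <- ((2 * n - 1) * cosang * p_n - (n - 1) * p_nm1) / n
    p_nm1 <- p_n
    p_n <- p_np1
    g <- g + (2 * n + 1) / (n^m * (n + 1)^m) * p_n
  }
  g / (4 * pi)
}

#' Spherical-spline interpolation of bad channels
#'
#' Reconstructs the signal at `bad` channel sites from the remaining channels
#' with a surface spline on the unit sphere (stiffness 4), the standard EEG
#' approach for repairing a small number of noisy electrodes.
#'
#' @param values channels x samples numeric matrix (rows follow `labels`).
#' @param labels channel labels for the rows of `values`.
#' @param bad labels (or indices) of channels to reconstruct.
#' @param lambda ridge regularization added to the spline system.
#' @return `values` with the bad rows replaced by their interpolation.
#' @export
spline_interpolate <- function(values, labels, bad, lambda = 1e-5) {
  if (is.character(bad)) bad <- match(bad, labels)
  assert_that(!anyNA(bad) && all(bad >= 1 & bad <= length(labels)),
              "bad channels must name channels present in `labels`")
  bad <- unique(as.integer(bad))
  good <- setdiff(seq_along(labels), bad)
  assert_that(length(good) >= 4, "need at least 4 good channels to interpolate")

  pos <- standard_montage(labels)
  xyz <- as.matrix(pos[, c("x", "y", "z")])
  cos_gg <- pmin(pmax(xyz[good, , drop = FALSE] %*% t(xyz[good, , drop = FALSE]), -1), 1)
  cos_bg <- pmin(pmax(xyz[bad, , drop = FALSE] %*% t(xyz[good, , drop = FALSE]), -1), 1)

  G <- matrix(.spline_g(cos_gg), nrow = length(good))
  Gb <- matrix(.spline_g(cos_bg), nrow = length(bad))

  ng <- length(good)
  A <- rbind(cbind(G + diag(lambda, ng), rep(1, ng)),
             c(rep(1, ng), 0))
  rhs <- rbind(values[good, , drop = FALSE], 0)
  sol <- solve(A, rhs)
  w <- sol[seq_len(ng), , drop = FALSE]
  c0 <- sol[ng + 1, ]
  values[bad, ] <- Gb %*% w + matrix(c0, nrow = length(bad),
                                     ncol = ncol(values), byrow = TRUE)
  values
}

# Nearest neighbors by angular distance (used for neighbor-based checks).
channel_neighbors <- function(labels, k = 4) {
  pos <- standard_montage(labels)
  xyz <- as.matrix(pos[, c("x", "y", "z")])
  cosang <- xyz %*% t(xyz)
  lapply(seq_along(labels), function(i) {
    ord <- order(cosang[i, ], decreasing = TRUE)
    setdiff(ord, i)[seq_len(k)]
  })
}
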