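# Shared fixture builders; everything is generated in code at test time.

AA_NO_PRO <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "Q", "R", "S", "T", "V", "W", "Y")

random_shift_table <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  shift_table(tibble::tibble(
    residue = seq_len(n),
    aa = sample(AA_NO_PRO, n, replace = TRUE),
    H = runif(n, 7.5, 9.5),
    N = runif(n, 106, 130)))
}

random_peaklist <- function(n, seed = NULL, heights = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  peaklist(tibble::tibble(
    label = sprintf("X%dN-H", seq_len(n)),
    w1 = runif(n, 106, 130),
    w2 = runif(n, 7.5, 9.5),
    height = if (heights) runif(n, 1e5, 1e7) else NA_real_))
}

# exhaustive double-loop reference for the minimal-shift map
minimal_shift_oracle <- function(free, bound, alpha = 0.2) {
  assigned <- free[!is.na(free$H) & !is.na(free$N), ]
  ms <- numeric(nrow(assigned))
  idx <- integer(nrow(assigned))
  for (i in seq_len(nrow(assigned))) {
    best <- Inf
    best_j <- NA_integer_
    for (j in seq_len(nrow(bound))) {
      d <- sqrt((assigned$H[i] - bound$w2[j])^2 +
                  ((assigned$N[i] - bound$w1[j]) * alpha)^2)
      if (d < best) {
        best <- d
        best_j <- j
      }
    }
    ms[i] <- best
    idx[i] <- best_j
  }
  list(residue = assigned$residue, min_shift = ms, bound_peak = idx)
}

# numerical-minimization reference for rigid superposition: optimize
# Euler angles + translation with several restarts
superpose_oracle_rmsd <- function(A, B, n_starts = 8) {
  rot <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(p) {
    Rt <- rot(p[1:3])
    moved <- sweep(A %*% t(Rt), 2, p[4:6], "+")
    sqrt(mean(rowSums((moved - B)^2)))
  }
  best <- Inf
  for (s in seq_len(n_starts)) {
    p0 <- c(runif(3, -pi, pi), colMeans(B) - colMeans(A))
    fit <- optim(p0, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

dkk4_flexible_truth <- list(c(19, 40), c(98, 139), c(220, 224))

# largest absolute deviation between recovered flexible segment bounds
# and the planted truth (Inf when counts differ)
boundary_error <- function(segments, truth = dkk4_flexible_truth) {
  flex <- segments[segments$label == "flexible", ]
  if (nrow(flex) != length(truth)) return(Inf)
  max(vapply(seq_along(truth), function(i) {
    max(abs(c(flex$start[i], flex$end[i]) - truth[[i]]))
  }, numeric(1)))
}

as_tibble_ens <- function(x) tibble::as_tibble(as.data.frame(x))
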