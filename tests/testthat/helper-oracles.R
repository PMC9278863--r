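# Independent oracles used to cross-check the package's geometry code.
# These deliberately take different algorithmic routes than the
# implementation (quaternion eigen-decomposition instead of SVD, explicit
# double loops instead of vectorized matrix algebra).

# quaternion -> rotation matrix
quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# Horn (1987) closed-form quaternion superposition of mobile onto reference
horn_superpose <- function(mobile, reference) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  M <- sweep(mobile, 2, cm); R <- sweep(reference, 2, cr)
  S <- t(M) %*% R
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[1,3]+S[3,1],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[1,3]+S[3,1],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  ev <- eigen(K, symmetric = TRUE)
  rot <- quat_to_rot(ev$vectors[, 1])
  moved <- M %*% t(rot)
  list(rotation = rot, translation = cr - as.numeric(rot %*% cm),
       rmsd = sqrt(mean(rowSums((moved - R)^2))))
}

# rotation angle via the complex eigenvalues of R (e^{+-i theta})
rotation_angle_eigen <- function(R) {
  ev <- eigen(R)$values
  max(abs(Arg(ev))) * 180 / pi
}

# uniform random rotation via quaternion sampling
random_rotation <- function() quat_to_rot(stats::rnorm(4))

random_rigid <- function() {
  rigid_transform(random_rotation(), stats::runif(3, -20, 20))
}

# naive double-loop distance matrix
brute_distance_matrix <- function(xyz) {
  n <- nrow(xyz)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    m[i, j] <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  m
}

# naive RMS over a block of a residue-level difference matrix
brute_block_rms <- function(d, rows, cols, skip_diag = FALSE) {
  vals <- c()
  for (i in rows) for (j in cols) {
    if (skip_diag && j >= i) next
    vals <- c(vals, d[i, j])
  }
  sqrt(mean(vals^2))
}

# brute-force translation-scan objective: move the domain, then measure
brute_scan_objective <- function(s, segments, transport, constraints, normal,
                                 ts, chain = "A") {
  seg <- bundlemotion:::assign_segments(s, segments)
  moving <- !s$het & s$chain == chain & !is.na(seg) &
    seg %in% transport$members
  vapply(ts, function(t) {
    s2 <- s
    s2[moving, c("x", "y", "z")] <-
      as.matrix(s[moving, c("x", "y", "z")]) +
      matrix(t * normal, sum(moving), 3, byrow = TRUE)
    total <- 0
    for (k in seq_len(nrow(constraints))) {
      pi <- s2[s2$resno == constraints$i[k] & s2$elety == "CA" & s2$chain == chain, c("x","y","z")]
      pj <- s2[s2$resno == constraints$j[k] & s2$elety == "CA" & s2$chain == chain, c("x","y","z")]
      total <- total + sqrt(sum((as.numeric(pi) - as.numeric(pj))^2))
    }
    total
  }, numeric(1))
}

# algebraic (Kasa) least-squares circle fit in a plane; returns the radius
circle_fit_radius <- function(xy) {
  A <- cbind(2 * xy[, 1], 2 * xy[, 2], 1)
  b <- xy[, 1]^2 + xy[, 2]^2
  sol <- solve(crossprod(A), crossprod(A, b))
  sqrt(sol[3] + sol[1]^2 + sol[2]^2)
}
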