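# shared fixtures, all built in code

# unit right tetrahedron (volume 1/6)
unit_tet <- function() {
  tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
           matrix(1:4, 1), "muscle")
}

# structured cube mesh on [0, L]^3, n divisions per edge (6 tets per hex)
cube_mesh <- function(n = 2L, L = 1, part = "muscle") {
  s <- seq(0, L, length.out = n + 1L)
  nid <- array(seq_len((n + 1L)^3), rep(n + 1L, 3))
  coords <- as.matrix(expand.grid(x = s, y = s, z = s))
  hex_tets <- rbind(c(1, 2, 4, 8), c(1, 2, 8, 6), c(1, 6, 8, 5),
                    c(1, 4, 3, 8), c(1, 3, 7, 8), c(1, 7, 5, 8))
  elems <- NULL
  for (kz in 1:n) for (j in 1:n) for (i in 1:n) {
    corners <- c(nid[i, j, kz], nid[i + 1, j, kz], nid[i, j + 1, kz],
                 nid[i + 1, j + 1, kz], nid[i, j, kz + 1],
                 nid[i + 1, j, kz + 1], nid[i, j + 1, kz + 1],
                 nid[i + 1, j + 1, kz + 1])
    elems <- rbind(elems, matrix(corners[t(hex_tets)], 6, 4, byrow = TRUE))
  }
  suppressWarnings(tet_mesh(coords, elems, rep(part, nrow(elems))))
}

# rebuild a deformation state from a given right Cauchy-Green tensor
state_from_C <- function(C, a0 = c(1, 0, 0)) {
  eg <- eigen(C, symmetric = TRUE)
  Fs <- eg$vectors %*% diag(sqrt(eg$values)) %*% t(eg$vectors)
  deformation_state(Fs, a0)
}

# independent strain-energy oracle for alpha = 0 parameter sets:
# W = c1 I3^(-1/3) I1 + c2 I3^(-2/3) I2 - 3 c1 - 3 c2 + k/2 (J-1)^2
#     + (1-gamma) c3 (L^c4 / c4 - ln L - 1/c4) for L >= 1
energy_oracle <- function(C, a0, pr) {
  I1 <- sum(diag(C))
  I2 <- (I1^2 - sum(C * C)) / 2
  I3 <- det(C)
  J <- sqrt(I3)
  lam <- sqrt(as.numeric(a0 %*% C %*% a0))
  W <- pr$c1 * I3^(-1 / 3) * I1 + pr$c2 * I3^(-2 / 3) * I2 -
    3 * pr$c1 - 3 * pr$c2 + pr$bulk_k / 2 * (J - 1)^2
  if (pr$gamma != 1 && lam >= 1)
    W <- W + pr$c3 * (lam^pr$c4 / pr$c4 - log(lam) - 1 / pr$c4)
  W
}

# S = 2 dW/dC by central differences of the energy oracle
second_pk_fd <- function(C, a0, pr, h = 1e-6) {
  S <- matrix(0, 3, 3)
  for (k in 1:3) for (l in k:3) {
    dC <- matrix(0, 3, 3)
    if (k == l) dC[k, k] <- h else dC[k, l] <- dC[l, k] <- h / 2
    # symmetric perturbation with total magnitude h: S_kl = 2 dW/dC_kl
    S[k, l] <- S[l, k] <- (energy_oracle(C + dC, a0, pr) -
                           energy_oracle(C - dC, a0, pr)) / h
  }
  S
}

random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
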