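# Shared fixtures built in code.

# minimal frame with the default classification atoms at chosen distances:
# OG at origin, oxyanion N at (3,0,0); ester O placed at d_no from N along
# +x, ester C placed so that |OG-C| = d_ogc (along +x from OG when possible)
toy_class_frame <- function(d_no, d_ogc) {
  og <- c(0, 0, 0); nn <- c(3, 0, 0)
  oo <- nn + c(d_no, 0, 0)
  cc <- og + c(d_ogc, 0, 0)
  md_frame(resno = c(131L, 132L, 500L, 500L),
           resname = c("SER", "MET", "MHT", "MHT"),
           atom = c("OG", "N", "C1", "O1"),
           x = c(og[1], nn[1], cc[1], oo[1]),
           y = c(og[2], nn[2], cc[2], oo[2]),
           z = c(og[3], nn[3], cc[3], oo[3]))
}

# salt-bridge frame with a single NZ / OD1,OD2 pair at a set minimum distance
toy_sb_frame <- function(dmin) {
  md_frame(resno = c(148L, 233L, 233L), resname = c("LYS", "ASP", "ASP"),
           atom = c("NZ", "OD1", "OD2"),
           x = c(0, dmin, dmin + 2.2), y = c(0, 0, 0), z = c(0, 0, 0))
}

# small rigid 'protein' used for superposition tests
toy_structure <- function(n = 20, seed = 42) {
  petkit:::with_seed(seed, {
    md_frame(resno = seq_len(n), resname = rep("ALA", n),
             atom = rep("CA", n),
             x = stats::rnorm(n, sd = 5), y = stats::rnorm(n, sd = 5),
             z = stats::rnorm(n, sd = 5))
  })
}

# apply an explicit rigid motion to a frame
transform_frame <- function(frame, R, tr) {
  X <- as.matrix(frame[, c("x", "y", "z")]) %*% t(R)
  X <- sweep(X, 2, tr, "+")
  md_frame(frame$resno, frame$resname, frame$atom, X[, 1], X[, 2], X[, 3])
}

rotation_xyz <- function(ax, ay, az) {
  Rx <- matrix(c(1, 0, 0, 0, cos(ax), sin(ax), 0, -sin(ax), cos(ax)), 3, 3)
  Ry <- matrix(c(cos(ay), 0, -sin(ay), 0, 1, 0, sin(ay), 0, cos(ay)), 3, 3)
  Rz <- matrix(c(cos(az), sin(az), 0, -sin(az), cos(az), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}
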