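# Flat grayscale morphology with the 4-connected unit cross, used by the
# granularity spectrum. Out-of-frame neighbours take the background value 0,
# consistent with masked images whose support is interior to the frame.
# Iterating the unit-cross erosion k times is erosion by the digital disc of
# radius k (the k-fold Minkowski sum of the cross), so successive openings
# form a granulometry and remove intensity monotonically.

.shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r_dst <- max(1L, 1L + dr):min(nr, nr + dr)
  c_dst <- max(1L, 1L + dc):min(nc, nc + dc)
  out[r_dst, c_dst] <- m[r_dst - dr, c_dst - dc]
  out
}

.erode_cross <- function(m) {
  pmin(m,
       .shift_mat(m, 1L, 0L), .shift_mat(m, -1L, 0L),
       .shift_mat(m, 0L, 1L), .shift_mat(m, 0L, -1L))
}

.dilate_cross <- function(m) {
  pmax(m,
       .shift_mat(m, 1L, 0L), .shift_mat(m, -1L, 0L),
       .shift_mat(m, 0L, 1L), .shift_mat(m, 0L, -1L))
}
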