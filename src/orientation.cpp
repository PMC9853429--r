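#include <Rcpp.h>
using namespace Rcpp;

// Propagate a body orientation through gyroscope rates and rotate the
// body-frame specific force into the world frame.
//
// gyro_rad: n x 3 angular rates (rad/s, body frame)
// accel:    n x 3 specific force (body frame)
// dt:       sample interval (s)
// R0:       3 x 3 initial orientation (body -> world) at the first sample
//
// Integration uses the trapezoid of consecutive angular rates and an exact
// Rodrigues rotation per step (constant axis within a step).
// [[Rcpp::export]]
NumericMatrix rotate_to_world(NumericMatrix gyro_rad, NumericMatrix accel,
                              double dt, NumericMatrix R0) {
  int n = gyro_rad.nrow();
  if (accel.nrow() != n) stop("gyro and accel must have equal length");
  NumericMatrix out(n, 3);
  double R[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) R[i][j] = R0(i, j);

  for (int k = 0; k < n; ++k) {
    // world accel at sample k with current orientation
    for (int i = 0; i < 3; ++i)
      out(k, i) = R[i][0] * accel(k, 0) + R[i][1] * accel(k, 1) +
                  R[i][2] * accel(k, 2);
    if (k == n - 1) break;

    double wx = 0.5 * (gyro_rad(k, 0) + gyro_rad(k + 1, 0)) * dt;
    double wy = 0.5 * (gyro_rad(k, 1) + gyro_rad(k + 1, 1)) * dt;
    double wz = 0.5 * (gyro_rad(k, 2) + gyro_rad(k + 1, 2)) * dt;
    double th = std::sqrt(wx * wx + wy * wy + wz * wz);
    double A[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
    if (th > 1e-12) {
      double ux = wx / th, uy = wy / th, uz = wz / th;
      double c = std::cos(th), s = std::sin(th), v = 1.0 - c;
      A[0][0] = c + ux * ux * v;
      A[0][1] = ux * uy * v - uz * s;
      A[0][2] = ux * uz * v + uy * s;
      A[1][0] = uy * ux * v + uz * s;
      A[1][1] = c + uy * uy * v;
      A[1][2] = uy * uz * v - ux * s;
      A[2][0] = uz * ux * v - uy * s;
      A[2][1] = uz * uy * v + ux * s;
      A[2][2] = c + uz * uz * v;
    }
    // body-frame composition: R <- R * A
    double Rn[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        Rn[i][j] = R[i][0] * A[0][j] + R[i][1] * A[1][j] + R[i][2] * A[2][j];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) R[i][j] = Rn[i][j];
  }
  return out;
}
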