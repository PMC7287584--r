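#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Madgwick gradient-descent orientation filter, IMU (gyro + accelerometer)
// variant. Quaternion q maps sensor-frame vectors into the earth frame
// (Hamilton convention, scalar first). Gyro input in rad/s, accelerometer in
// any consistent unit (only its direction is used). beta is the gradient step
// magnitude in rad/s. A zero-norm accelerometer sample propagates gyro-only.
// [[Rcpp::export]]
NumericMatrix madgwick_filter(NumericMatrix gyr_rad, NumericMatrix acc,
                              double sample_rate, double beta,
                              NumericVector q0) {
  const int n = gyr_rad.nrow();
  const double dt = 1.0 / sample_rate;
  NumericMatrix Q(n, 4);
  double q1 = q0[0], q2 = q0[1], q3 = q0[2], q4 = q0[3];
  {
    double nq = std::sqrt(q1*q1 + q2*q2 + q3*q3 + q4*q4);
    q1 /= nq; q2 /= nq; q3 /= nq; q4 /= nq;
  }
  for (int i = 0; i < n; ++i) {
    double gx = gyr_rad(i, 0), gy = gyr_rad(i, 1), gz = gyr_rad(i, 2);
    double ax = acc(i, 0), ay = acc(i, 1), az = acc(i, 2);

    // rate of change from gyroscope: 0.5 * q (x) (0, omega)
    double qDot1 = 0.5 * (-q2 * gx - q3 * gy - q4 * gz);
    double qDot2 = 0.5 * ( q1 * gx + q3 * gz - q4 * gy);
    double qDot3 = 0.5 * ( q1 * gy - q2 * gz + q4 * gx);
    double qDot4 = 0.5 * ( q1 * gz + q2 * gy - q3 * gx);

    double anorm = std::sqrt(ax*ax + ay*ay + az*az);
    if (anorm > 0.0) {
      ax /= anorm; ay /= anorm; az /= anorm;
      // objective: earth gravity (0,0,1) rotated into sensor frame minus
      // the measured (normalized) specific force
      double f1 = 2.0 * (q2 * q4 - q1 * q3) - ax;
      double f2 = 2.0 * (q1 * q2 + q3 * q4) - ay;
      double f3 = 2.0 * (0.5 - q2 * q2 - q3 * q3) - az;
      // gradient = J^T f
      double s1 = -2.0 * q3 * f1 + 2.0 * q2 * f2;
      double s2 =  2.0 * q4 * f1 + 2.0 * q1 * f2 - 4.0 * q2 * f3;
      double s3 = -2.0 * q1 * f1 + 2.0 * q4 * f2 - 4.0 * q3 * f3;
      double s4 =  2.0 * q2 * f1 + 2.0 * q3 * f2;
      double snorm = std::sqrt(s1*s1 + s2*s2 + s3*s3 + s4*s4);
      if (snorm > 0.0) {
        qDot1 -= beta * s1 / snorm;
        qDot2 -= beta * s2 / snorm;
        qDot3 -= beta * s3 / snorm;
        qDot4 -= beta * s4 / snorm;
      }
    }

    q1 += qDot1 * dt; q2 += qDot2 * dt; q3 += qDot3 * dt; q4 += qDot4 * dt;
    double nq = std::sqrt(q1*q1 + q2*q2 + q3*q3 + q4*q4);
    q1 /= nq; q2 /= nq; q3 /= nq; q4 /= nq;
    Q(i, 0) = q1; Q(i, 1) = q2; Q(i, 2) = q3; Q(i, 3) = q4;
  }
  return Q;
}
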