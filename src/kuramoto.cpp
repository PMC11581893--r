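#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Explicit-Euler integration of the Kuramoto phase model
//   dtheta_i/dt = omega_i + lambda * sum_j A_ij sin(theta_j - theta_i)
// on a binary adjacency matrix. The pairwise sine coupling is evaluated via
//   sum_j A_ij sin(theta_j - theta_i)
//     = cos(theta_i) (A sin(theta))_i - sin(theta_i) (A cos(theta))_i,
// so each step costs two matrix-vector products and one sin/cos sweep.
// Phases are integrated unwrapped (the coupling is wrap-invariant).
//
// The order parameter r e^{i Psi} = mean_j e^{i theta_j} is recorded at every
// step m = 0..n_steps (time m*dt); only samples with m >= first_kept are
// returned.
// [[Rcpp::export]]
List kuramoto_euler(const arma::mat& A, const arma::vec& theta0,
                    const arma::vec& omega, double lambda, double dt,
                    int n_steps, int first_kept) {
    const int N = A.n_rows;
    if ((int)theta0.n_elem != N || (int)omega.n_elem != N)
        stop("theta0/omega length does not match the adjacency dimension");
    if (first_kept < 0 || first_kept > n_steps)
        stop("first_kept must lie in [0, n_steps]");

    arma::vec theta = theta0;
    const int n_keep = n_steps - first_kept + 1;
    arma::vec r_out(n_keep), psi_out(n_keep);

    int out = 0;
    for (int m = 0; m <= n_steps; ++m) {
        arma::vec s = arma::sin(theta);
        arma::vec c = arma::cos(theta);
        if (m >= first_kept) {
            double ms = arma::mean(s), mc = arma::mean(c);
            r_out(out) = std::sqrt(ms * ms + mc * mc);
            psi_out(out) = std::atan2(ms, mc);
            ++out;
        }
        if (m == n_steps) break;
        if (lambda != 0.0) {
            arma::vec As = A * s;
            arma::vec Ac = A * c;
            theta += dt * (omega + lambda * (c % As - s % Ac));
        } else {
            theta += dt * omega;
        }
        if (!theta.is_finite())
            stop("non-finite phases at integration step %d", m + 1);
    }
    return List::create(_["r"] = r_out, _["psi"] = psi_out);
}
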