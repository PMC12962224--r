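#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// M x N kernel matrix of component signal responses:
//   k(m, n) = exp(-b : D(omega_cent)) * (1 - exp(-TR * R1)) * exp(-TE * R2)
// with the axisymmetric Lorentzian eigenvalues evaluated at each
// measurement's centroid frequency. comps columns follow the canonical
// order (d_par, d_perp, theta, phi, d0, gamma_par, gamma_perp, r1, r2).
// [[Rcpp::export]]
arma::mat kernel_cpp(const arma::vec& b, const arma::vec& b_delta,
                     const arma::vec& theta_enc, const arma::vec& phi_enc,
                     const arma::vec& omega_cent, const arma::vec& te,
                     const arma::vec& tr, const arma::mat& comps)
{
    const arma::uword M = b.n_elem, N = comps.n_rows;
    arma::mat K(M, N);

    arma::vec uex = arma::sin(theta_enc) % arma::cos(phi_enc);
    arma::vec uey = arma::sin(theta_enc) % arma::sin(phi_enc);
    arma::vec uez = arma::cos(theta_enc);
    arma::vec om2 = arma::square(omega_cent);

    for (arma::uword n = 0; n < N; ++n) {
        const double d_par = comps(n, 0), d_perp = comps(n, 1);
        const double th = comps(n, 2), ph = comps(n, 3);
        const double d0 = comps(n, 4);
        const double g_par2 = comps(n, 5) * comps(n, 5);
        const double g_perp2 = comps(n, 6) * comps(n, 6);
        const double r1 = comps(n, 7), r2 = comps(n, 8);
        const double ux = std::sin(th) * std::cos(ph);
        const double uy = std::sin(th) * std::sin(ph);
        const double uz = std::cos(th);
        for (arma::uword m = 0; m < M; ++m) {
            const double lp = d_par + (d0 - d_par) * om2(m) / (om2(m) + g_par2);
            const double lq = d_perp + (d0 - d_perp) * om2(m) / (om2(m) + g_perp2);
            const double c = uex(m) * ux + uey(m) * uy + uez(m) * uz;
            const double cos2 = c * c;
            const double expo = b(m) * ((1.0 - b_delta(m)) * (lp + 2.0 * lq) / 3.0
                                        + b_delta(m) * (lq + (lp - lq) * cos2));
            K(m, n) = std::exp(-expo) * (1.0 - std::exp(-tr(m) * r1))
                      * std::exp(-te(m) * r2);
        }
    }
    return K;
}
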