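#define ARMA_WARN_LEVEL 1
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Lawson-Hanson active-set nonnegative least squares,
//   argmin_{x >= 0} || A x - b ||_2.
// The gradient is evaluated as A'(b - A x) (cheap because x is sparse on
// the passive set) and the passive-set subproblems solve the normal
// equations with cross-product columns computed on demand and cached.
// `init` (0-based column indices) warm-starts the passive set — used by the
// iterative inversions, whose previous retained set is already
// near-optimal; the result is still an exact KKT point because the passive
// set is re-solved and then the standard optimality loop runs to
// convergence. Termination on the dual-feasibility condition with
// tolerance `tol` scaled by the gradient magnitude at x = 0; ties in the
// entering-variable choice resolve to the lowest column index.
// [[Rcpp::export]]
Rcpp::List nnls_cpp(const arma::mat& A, const arma::vec& b, double tol = 1e-12,
                    Rcpp::Nullable<Rcpp::IntegerVector> init = R_NilValue)
{
    const arma::uword n = A.n_cols;
    const arma::vec Atb = A.t() * b;

    arma::mat AtA(n, n, arma::fill::none);   // filled column-by-column
    std::vector<bool> have_col(n, false);
    auto ensure_col = [&](arma::uword j) {
        if (!have_col[j]) { AtA.col(j) = A.t() * A.col(j); have_col[j] = true; }
    };

    arma::vec x(n, arma::fill::zeros);
    std::vector<bool> passive(n, false);

    const double scale = std::max(1.0, arma::norm(Atb, "inf"));
    const double wtol = tol * scale;
    const int max_inner = 3 * static_cast<int>(n) + 50;

    auto solve_passive = [&](const arma::uvec& P, arma::vec& z) -> bool {
        const arma::uword np = P.n_elem;
        arma::mat App(np, np);
        for (arma::uword k = 0; k < np; ++k) {
            ensure_col(P(k));
            const double* col = AtA.colptr(P(k));
            for (arma::uword i = 0; i < np; ++i) App(i, k) = col[P(i)];
        }
        const arma::vec bp = Atb.elem(P);
        if (arma::solve(z, App, bp, arma::solve_opts::likely_sympd +
                                    arma::solve_opts::no_approx))
            return true;
        return arma::solve(z, App, bp);  // rank-deficient fallback
    };

    // restore primal feasibility on the current passive set; returns false
    // if the subproblem could not be solved (caller drops the entering
    // column)
    auto inner_restore = [&]() -> bool {
        int inner = 0;
        while (inner++ < max_inner) {
            arma::uvec P(n);
            arma::uword np = 0;
            for (arma::uword j = 0; j < n; ++j) if (passive[j]) P(np++) = j;
            P.resize(np);
            if (np == 0) { x.zeros(); return true; }

            arma::vec z;
            if (!solve_passive(P, z)) return false;

            if (z.min() > 0.0) {
                x.zeros();
                x(P) = z;
                return true;
            }
            double alpha = 1.0;
            for (arma::uword k = 0; k < np; ++k) {
                if (z(k) <= 0.0) {
                    const double xi = x(P(k));
                    const double a = xi / (xi - z(k));
                    if (a < alpha) alpha = a;
                }
            }
            for (arma::uword k = 0; k < np; ++k)
                x(P(k)) += alpha * (z(k) - x(P(k)));
            for (arma::uword k = 0; k < np; ++k) {
                if (x(P(k)) <= 1e-14 * scale) { x(P(k)) = 0.0; passive[P(k)] = false; }
            }
        }
        return true;
    };

    auto gradient = [&](arma::vec& w) {
        arma::uvec P(n);
        arma::uword np = 0;
        for (arma::uword j = 0; j < n; ++j) if (passive[j] && x(j) > 0) P(np++) = j;
        P.resize(np);
        if (np == 0) w = Atb;
        else w = Atb - A.t() * (A.cols(P) * x.elem(P));
    };

    if (init.isNotNull()) {
        Rcpp::IntegerVector iv(init);
        for (int k = 0; k < iv.size(); ++k) {
            const int j = iv[k];
            if (j >= 0 && j < static_cast<int>(n)) passive[j] = true;
        }
        inner_restore();
    }

    arma::vec w;
    gradient(w);

    const int max_outer = 3 * static_cast<int>(n) + 50;
    int outer = 0;
    while (outer++ < max_outer) {
        int t = -1;
        double wmax = wtol;
        for (arma::uword j = 0; j < n; ++j) {
            if (!passive[j] && w(j) > wmax) { wmax = w(j); t = static_cast<int>(j); }
        }
        if (t < 0) break;  // KKT satisfied
        passive[t] = true;
        if (!inner_restore()) passive[t] = false;
        gradient(w);
    }

    const double resid = arma::norm(b - A * x, 2);
    return Rcpp::List::create(Rcpp::Named("x") = x,
                              Rcpp::Named("residual") = resid);
}
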