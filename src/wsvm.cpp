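#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Weighted L2-regularized squared-hinge linear SVM, Newton method with
// backtracking line search. Objective:
//   f(w,b) = 0.5 * w'w + C * sum_i u_i * max(0, 1 - y_i (x_i'w + b))^2
// The bias is unpenalized. Squared hinge makes f once-differentiable with a
// generalized Hessian, so damped Newton converges in a handful of steps.

static double obj_fun(const mat& X, const vec& y, const vec& u, double C,
                      const vec& w, double b, vec& margin) {
    margin = 1.0 - y % (X * w + b);
    vec xi = clamp(margin, 0.0, datum::inf);
    return 0.5 * dot(w, w) + C * dot(u, xi % xi);
}

// [[Rcpp::export(name = ".wsvm_fit")]]
Rcpp::List wsvm_fit(const arma::mat& X, const arma::vec& y, const arma::vec& u,
                    double C, const arma::vec& w0, double b0,
                    int max_iter = 50, double tol = 1e-9) {
    const uword p = X.n_cols;
    vec w = w0;
    double b = b0;
    vec margin;
    double f = obj_fun(X, y, u, C, w, b, margin);

    for (int it = 0; it < max_iter; ++it) {
        uvec act = find(margin > 0);
        vec grad_w = w;
        double grad_b = 0.0;
        if (act.n_elem > 0) {
            vec coef = -2.0 * C * (u.elem(act) % y.elem(act) % margin.elem(act));
            grad_w += X.rows(act).t() * coef;
            grad_b = accu(coef);
        }
        double gnorm = std::sqrt(dot(grad_w, grad_w) + grad_b * grad_b);
        if (gnorm < tol * std::max(1.0, std::abs(f))) break;

        // Generalized Hessian on the active set (plus identity for w-block)
        mat H(p + 1, p + 1, fill::zeros);
        H.submat(0, 0, p - 1, p - 1) = eye(p, p);
        if (act.n_elem > 0) {
            mat Xa = X.rows(act);
            vec ua = 2.0 * C * u.elem(act);
            mat XaU = Xa.each_col() % ua;
            H.submat(0, 0, p - 1, p - 1) += Xa.t() * XaU;
            vec cross = Xa.t() * ua;
            H.submat(0, p, p - 1, p) = cross;
            H.submat(p, 0, p, p - 1) = cross.t();
            H(p, p) = accu(ua);
        } else {
            H(p, p) = 1.0;  // keep the system nonsingular; grad_b is 0 here
        }
        vec g(p + 1);
        g.head(p) = grad_w;
        g(p) = grad_b;
        vec step;
        if (!solve(step, H, -g, solve_opts::likely_sympd)) break;

        double t = 1.0, f_new = 0.0;
        vec w_new;
        double b_new = 0.0;
        vec margin_new;
        bool ok = false;
        for (int ls = 0; ls < 30; ++ls) {
            w_new = w + t * step.head(p);
            b_new = b + t * step(p);
            f_new = obj_fun(X, y, u, C, w_new, b_new, margin_new);
            if (f_new <= f + 1e-4 * t * dot(g, step)) { ok = true; break; }
            t *= 0.5;
        }
        if (!ok) break;
        double df = f - f_new;
        w = w_new; b = b_new; f = f_new; margin = margin_new;
        if (df < tol * std::max(1.0, std::abs(f))) break;
    }

    return Rcpp::List::create(Rcpp::Named("w") = w,
                              Rcpp::Named("b") = b,
                              Rcpp::Named("objective") = f);
}
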