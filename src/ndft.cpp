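#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Exact non-uniform DFT of a time-varying 2D object along radial spokes.
//
// For spoke m (angle rho_m, radians) and readout sample i:
//   S[i, m, ch] = ramp_m(kr_i) * exp(i phi0_m) *
//                 sum_j sens[j, ch] * mag_j *
//                 exp(i (bg0_j + s_m bg1_j + a_m heat_j)) *
//                 exp(-2 i pi kr_i u_j),  u_j = ux_j cos(rho_m) + uy_j sin(rho_m)
// with ramp_m the rigid-shift phase ramp
//   exp(-2 i pi kr_i (dx_m cos rho_m + dy_m sin rho_m)),
// ux, uy, dx, dy in FoV units.  kr must be uniformly spaced (the per-sample
// phase is advanced by a constant complex factor per voxel, which keeps the
// transform exact while avoiding a complex exponential per sample).
// [[Rcpp::export]]
arma::cx_cube ndft_simulate(const arma::vec& mag,
                            const arma::cx_mat& sens,
                            const arma::vec& bg0,
                            const arma::vec& bg1,
                            const arma::vec& heat,
                            const arma::vec& ux,
                            const arma::vec& uy,
                            const arma::vec& kr,
                            const arma::vec& rho_rad,
                            const arma::vec& s_t,
                            const arma::vec& a_t,
                            const arma::vec& phi0_t,
                            const arma::vec& dx_fov,
                            const arma::vec& dy_fov) {
    const uword n_chan = sens.n_cols;
    const uword n_read = kr.n_elem;
    const uword n_spokes = rho_rad.n_elem;
    const double two_pi = 2.0 * datum::pi;
    const double dk = n_read > 1 ? kr(1) - kr(0) : 0.0;
    const cx_double I(0.0, 1.0);

    cx_cube out(n_read, n_spokes, n_chan);
    cx_mat S(n_read, n_chan);

    for (uword m = 0; m < n_spokes; ++m) {
        const double co = std::cos(rho_rad(m));
        const double si = std::sin(rho_rad(m));
        vec u = ux * co + uy * si;

        // object at t_m (magnitude times phase), per voxel
        vec ph = bg0 + s_t(m) * bg1 + a_t(m) * heat;
        cx_vec obj = mag % exp(I * ph);

        // start at kr[0], advance by dk per sample
        cx_vec start = exp((-I * two_pi * kr(0)) * u);
        cx_vec w = exp((-I * two_pi * dk) * u);
        cx_mat V = sens.each_col() % (obj % start);

        const uword n_vox = mag.n_elem;
        const cx_double* wp = w.memptr();
        for (uword i = 0; i < n_read; ++i) {
            const bool advance = (i + 1 < n_read);
            for (uword ch = 0; ch < n_chan; ++ch) {
                cx_double* vc = V.colptr(ch);
                cx_double acc(0.0, 0.0);
                if (advance) {
                    for (uword j = 0; j < n_vox; ++j) {
                        acc += vc[j];
                        vc[j] *= wp[j];
                    }
                } else {
                    for (uword j = 0; j < n_vox; ++j) acc += vc[j];
                }
                S(i, ch) = acc;
            }
        }

        // rigid-motion phase ramp and global (drift) phase
        const double ud = dx_fov(m) * co + dy_fov(m) * si;
        cx_vec ramp = exp((-I * two_pi * ud) * conv_to<cx_vec>::from(kr));
        ramp *= std::exp(I * phi0_t(m));
        for (uword ch = 0; ch < n_chan; ++ch) {
            out.slice(ch).col(m) = S.col(ch) % ramp;
        }
    }
    return out;
}
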