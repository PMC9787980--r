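"""Independent reference solver for the seawater CO2 system.

Solves the full acid-base speciation for free-scale [H+] with explicit
sulfate and fluoride terms using scipy's brentq, then reports pCO2.
Constants: Millero (2006) K1/K2 (SWS), Dickson (1990b) KB (total),
Millero (1995) KW (SWS), Dickson (1990a) KS (free), Dickson & Riley
(1979) KF (free), Weiss (1974) K0, Uppstrom boron.

Used once to freeze reference values into tests/testthat fixtures.
"""
import numpy as np
from scipy.optimize import brentq


def kconstants(T, S):
    TK = T + 273.15
    lnTK = np.log(TK)
    sq = np.sqrt(S)
    # Millero 2006 K1/K2, seawater scale
    pK1 = (-126.34048 + 6320.813 / TK + 19.568224 * lnTK
           + 13.4191 * sq + 0.0331 * S - 5.33e-5 * S**2
           + (-530.123 * sq - 6.103 * S) / TK
           - 2.06950 * sq * lnTK)
    pK2 = (-90.18333 + 5143.692 / TK + 14.613358 * lnTK
           + 21.0894 * sq + 0.1248 * S - 3.687e-4 * S**2
           + (-772.483 * sq - 20.051 * S) / TK
           - 3.3336 * sq * lnTK)
    K1_sws, K2_sws = 10.0**-pK1, 10.0**-pK2
    # Dickson 1990b KB, total scale
    lnKB = ((-8966.90 - 2890.53 * sq - 77.942 * S + 1.728 * S**1.5
             - 0.0996 * S**2) / TK
            + 148.0248 + 137.1942 * sq + 1.62142 * S
            + (-24.4344 - 25.085 * sq - 0.2474 * S) * lnTK
            + 0.053105 * sq * TK)
    KB_tot = np.exp(lnKB)
    # Millero 1995 KW, seawater scale
    lnKW = (148.9802 - 13847.26 / TK - 23.6521 * lnTK
            + (118.67 / TK - 5.977 + 1.0495 * lnTK) * sq - 0.01615 * S)
    KW_sws = np.exp(lnKW)
    # Dickson 1990a KS, free scale
    IS = 19.924 * S / (1000.0 - 1.005 * S)
    lnKS = (-4276.1 / TK + 141.328 - 23.093 * lnTK
            + (-13856.0 / TK + 324.57 - 47.986 * lnTK) * np.sqrt(IS)
            + (35474.0 / TK - 771.54 + 114.723 * lnTK) * IS
            - 2698.0 / TK * IS**1.5 + 1776.0 / TK * IS**2
            + np.log(1.0 - 0.001005 * S))
    KS = np.exp(lnKS)
    # Dickson & Riley 1979 KF, free scale
    lnKF = 1590.2 / TK - 12.641 + 1.525 * np.sqrt(IS) + np.log(1.0 - 0.001005 * S)
    KF = np.exp(lnKF)
    TB = 0.0004157 * S / 35.0
    TS = 0.02824 * S / 35.0
    TF = 0.00007 * S / 35.0
    # scale conversions to free scale
    sws2free = 1.0 / (1.0 + TS / KS + TF / KF)
    tot2free = 1.0 / (1.0 + TS / KS)
    K1 = K1_sws * sws2free
    K2 = K2_sws * sws2free
    KB = KB_tot * tot2free
    KW = KW_sws * sws2free
    # Weiss 1974 K0, mol kg-1 atm-1
    lnK0 = (-60.2409 + 93.4517 * (100.0 / TK) + 23.3585 * np.log(TK / 100.0)
            + S * (0.023517 - 0.023656 * (TK / 100.0)
                   + 0.0047036 * (TK / 100.0)**2))
    K0 = np.exp(lnK0)
    return dict(K1=K1, K2=K2, KB=KB, KW=KW, KS=KS, KF=KF,
                TB=TB, TS=TS, TF=TF, K0=K0)


def ta_residual(hf, ta, dic, k):
    denom = hf**2 + k["K1"] * hf + k["K1"] * k["K2"]
    hco3 = dic * k["K1"] * hf / denom
    co3 = dic * k["K1"] * k["K2"] / denom
    boh4 = k["TB"] * k["KB"] / (k["KB"] + hf)
    oh = k["KW"] / hf
    hso4 = k["TS"] * hf / (k["KS"] + hf)
    hfl = k["TF"] * hf / (k["KF"] + hf)
    return hco3 + 2.0 * co3 + boh4 + oh - hf - hso4 - hfl - ta


def pco2_from_ta_dic(ta_umol, dic_umol, T, S):
    ta = ta_umol * 1e-6
    dic = dic_umol * 1e-6
    k = kconstants(T, S)
    hf = brentq(ta_residual, 1e-12, 1e-3, args=(ta, dic, k),
                xtol=1e-20, rtol=8.9e-16)
    co2aq = dic * hf**2 / (hf**2 + k["K1"] * hf + k["K1"] * k["K2"])
    return co2aq / k["K0"] * 1e6  # uatm


def main():
    rows = []
    for ta in np.linspace(2100, 2300, 5):
        for dic in np.linspace(1900, 2200, 5):
            for T in np.linspace(-1.8, 10.0, 5):
                rows.append((ta, dic, T, 32.0,
                             pco2_from_ta_dic(ta, dic, T, 32.0)))
    with open("tests/testthat/ref_carbonate_grid.csv", "w") as f:
        f.write("ta,dic,temperature,salinity,pco2_ref\n")
        for r in rows:
            f.write("%.1f,%.1f,%.2f,%.1f,%.6f\n" % r)
    # spot values
    print("pco2(ta=2200,dic=2000,T=0,S=32) =",
          repr(pco2_from_ta_dic(2200, 2000, 0.0, 32.0)))
    print("pco2(ta=2205,dic=2068,T=-1.28,S=31.9) =",
          repr(pco2_from_ta_dic(2205, 2068, -1.28, 31.9)))
    print("pco2(ta=2229,dic=2153,T=-1.61,S=32.2) =",
          repr(pco2_from_ta_dic(2229, 2153, -1.61, 32.2)))
    print("pco2(ta=2225,dic=2173,T=-1.71,S=32.1) =",
          repr(pco2_from_ta_dic(2225, 2173, -1.71, 32.1)))
    k = kconstants(0.0, 32.0)
    print("K0(T=0,S=32) mol/kg/atm =", repr(k["K0"]))
    # Weiss 1974 volumetric K0 (mol L-1 atm-1) for the flux solubility
    TK = 273.15
    lnK0v = (-58.0931 + 90.5069 * (100.0 / TK) + 22.2940 * np.log(TK / 100.0)
             + 32.0 * (0.027766 - 0.025888 * (TK / 100.0)
                       + 0.0050578 * (TK / 100.0)**2))
    print("K0vol(T=0,S=32) mol/L/atm =", repr(np.exp(lnK0v)))


if __name__ == "__main__":
    main()
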